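# podscan

Silique phenotyping from 3D point clouds of oilseed rape (*Brassica
napus*), by skeletonization and hierarchical segmentation.

## The problem

At the mature stage, the yield of an oilseed-rape plant sits in its
siliques — flat, elongate seed pods roughly 40–80 mm long and a few mm
across, packed on the terminal racemes of a branched stem system. Counting
and measuring them by hand is destructive and slow. Given a single-plant
laser scan (mm coordinates, gravity along +z, pot included or not),
`podscan` separates every silique from the stems and pot and reports the
plant's silique number (SN), total silique length (SL, mm) and total
silique volume (SV, mm³) — the traits that track seed yield.

## The method

1. **Preprocessing.** Statistical outlier filtering (mean k-nearest-neighbor
   distance thresholded at the global mean + 2 sd), then pot removal: the
   pot approximates an inverted frustum, so stacked z-slabs are fitted with
   least-squares circles; fitting climbs while the radius grows, and
   everything inside the circles up to the pot height is removed.
2. **Skeletonization.** The cloud contracts onto L1-median skeleton points:
   candidates seeded by random subsample move to a balance of attraction
   toward the kernel-weighted median of their source neighborhood,

   `x' = Σ p_j α_j / Σ α_j + τ λ · Σ (x − p_i) β_i / Σ β_i`,

   with Gaussian kernel weights `α_j = θ(‖x−p_j‖)/‖x−p_j‖`,
   `β_i = θ(‖x−p_i‖)/‖x−p_i‖²`, directionality `λ` (leading-eigenvalue
   fraction of the neighborhood covariance) scaling the repulsion from
   neighboring candidates, and a radius that grows each iteration until it
   wraps organ cross-sections. The neighborhood of every update is guarded
   against neighboring organs: only points *connected* to the candidate
   remain, and flat (silique-like) components are additionally restricted
   to a RANSAC-fitted plane slab of half-thickness `T_d`.
3. **Hierarchical segmentation.** DBSCAN clusters the skeleton points into
   classes; each class becomes an ordered polyline by greedy growth under
   a direction-corrected nearest-neighbor search (edges against the
   current tangent are inadmissible). Sub-skeletons whose facing ends are
   close (< 5 mean point spacings) and nearly collinear (< 15°) merge;
   interior vertices with edge angles ≤ 165° split.
4. **Traits.** Sub-skeletons longer than 200 mm (alone or chained with
   collinear pieces) are branches; remaining candidates are filtered to
   *effective siliques* whose length lies in
   `[max(15, μ − 1.96σ), μ + 1.96σ]`, with μ a middle-60% trimmed mean.
   Source points are assigned to each silique through the local constraint
   plane, and volume accumulates slab-wise as `L·W·(d₁+d₂)/2` from the
   projected bounding rectangles. SN, total SL and total SV are counts and
   sums over the effective siliques.

A fully labeled synthetic plant generator (three branch architectures,
raceme-packed flat pods, frustum pot, sector occlusion, sensor noise)
provides ground truth for every stage, so the whole pipeline is testable
without any scanned data.

## Worked example

```r
library(podscan)

plant  <- generate_plant(plant_spec(architecture = "FBBS",
                                    n_siliques = 30, seed = 101))
traits <- run_pipeline(plant$cloud, output_dir = "out")
traits
#> plant_traits: SN = 31 effective siliques (35 candidates, 5 branches)
#>   total SL = 1752.6 mm, total SV = 7263.4 mm^3

plant$truth$sn         # 30 siliques were generated
plant$truth$total_sl   # 1781.4 mm of true pod length
plant$truth$total_sv   # 8016.5 mm^3 of true pod volume
```

The estimated silique count lands within one pod of the truth, total
length agrees within two percent (skeleton lengths are tip-corrected),
and volume runs about ten percent low because the slab rectangles clip
the sector occlusion's missing faces. `out/` receives the skeleton CSV, the
sub-skeleton edge list, the labeled cloud (PLY, per-point silique id), the
per-silique table, a summary JSON embedding the resolved configuration,
and a log with per-stage timings.

A thin command-line wrapper ships in `inst/cli/podscan`
(`run`, `synth`, `eval`, `config` subcommands).

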