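---
title: "Skeleton-based silique phenotyping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-based silique phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podscan)
```

## The problem

A mature oilseed-rape (*Brassica napus*) plant carries its yield in
siliques — flat, elongate seed pods, typically 40–80 mm long and a few mm
across, borne in dense terminal racemes on a branched stem system. Counting
pods and measuring their lengths by hand is destructive and slow. Given a
single-plant 3D point cloud (laser scan, coordinates in mm, gravity along
+z), `podscan` separates the siliques from the stems and pot and returns
per-plant silique number (SN), total silique length (SL) and total silique
volume (SV).

The pipeline is a skeletonization-with-hierarchical-segmentation approach:

1. **Preprocess** — statistical outlier removal; pot detection by slab-wise
   least-squares circle fitting and removal of everything inside the fitted
   circles up to the pot height.
2. **Skeletonize** — iterative contraction of the cloud onto L1-median
   skeleton points, with each point's neighborhood restricted to a
   RANSAC-fitted plane slab so that adjacent organs do not contaminate each
   other as the neighborhood radius grows.
3. **Connect** — DBSCAN clustering of skeleton points into classes and
   greedy growth of one ordered polyline per class under a
   direction-corrected nearest-neighbor search (a weighted unidirectional
   graph: edges against the current tangent direction are inadmissible).
4. **Optimize** — merge sub-skeletons whose facing ends are close and
   nearly collinear; split sub-skeletons at sharp interior angles.
5. **Traits** — classify branches by length, filter effective siliques by
   a robust length interval, assign source points to each silique through
   the local constraint plane, and accumulate slab-wise volumes.

## Models and update rules

### L1-median contraction

A skeleton candidate at position $x$ with source neighborhood $J$ and
candidate neighborhood $I$ (both within the current radius $r$) moves to

$$x' \;=\; \frac{\sum_{j \in J} p_j\,\alpha_j}{\sum_j \alpha_j}
\;+\; \tau\,\lambda \,
\frac{\sum_{i \in I} (x - p_i)\,\beta_i}{\sum_i \beta_i},$$

with attraction weights $\alpha_j = \theta(\lVert x-p_j\rVert)/\lVert
x-p_j\rVert$, repulsion weights $\beta_i = \theta(\lVert
x-p_i\rVert)/\lVert x-p_i\rVert^2$, and the Gaussian kernel $\theta(d) =
\exp(-d^2/(r/2)^2)$. The directionality degree $\lambda \in [0,1]$ is the
leading-eigenvalue fraction of the neighborhood covariance; it approaches
1 on a line, so repulsion (which spreads candidates into an even chain)
acts where contraction has already succeeded. The balance $\tau$ defaults
to 0.35. Denominator distances are floored at $10^{-8}$ mm.

With a kernel much wider than the point spread the attraction term alone
iterates to the geometric median (the classic Weiszfeld fixed point); the
local kernel makes it a locally weighted median suitable for contraction.

### The neighborhood constraint

Siliques are flat and long, and neighboring pods can sit only a few mm
apart; as the radius grows, a candidate's neighborhood starts to catch
points of other organs, which would drag its median between them. The
guard has three interlocking parts, applied before every update:

1. **Connectivity.** Only the points connected to the candidate through
   links of at most `link_radius` (default 2 mm — above the organ
   thickness, below inter-organ gaps) remain: the interfering points of
   another organ are never connected to the candidate's own, whatever
   plane or radius is in play. This matters because no consensus score
   alone can reject a plane slicing through two parallel organs at once —
   such a plane's inliers are a superset of the correct plane's.
2. **Flatness gate.** The connected component's covariance decides whether
   the organ is flat: smallest-eigenvalue fraction at most
   `flat_ratio_max` (default 0.08). A silique stays flat at every radius;
   a stem's connected shell stops being flat once the radius wraps the
   tube.
3. **Plane slab.** Only for flat components, a RANSAC plane is fitted and
   both $J$ and $I$ are restricted to points strictly within $T_d$ of it
   (default 1.5 mm). The inlier tolerance defaults to 1 mm — deliberately
   *larger than the pod half-thickness*, so the refitted
   (total-least-squares) plane tracks the pod's mid-surface rather than
   one face. Round components skip the slab: a slab through a tube would
   pin its skeleton to the wall instead of letting it contract to the
   axis.

### Numerical schedule

The radius starts at $r_0$ (default twice the mean nearest-neighbor
spacing after downsampling to at most 50 000 points) and grows by
$0.5\,r_0$ per outer iteration until it reaches `r_final` (default 5 mm —
an organ-scale length: the contraction only engages once the radius wraps
a cross-section, so the end of the schedule must not depend on sampling
density). An explicit `max_outer_iters`/`inner_tol` pair can terminate on
mean movement instead, but by default the full schedule runs: before the
radius engages an organ, movement is spuriously small and an early exit
would freeze a half-contracted skeleton. Cleanup passes follow, all
documented defaults of `skeleton_params()`:

* **polish** (3 iterations): pure-attraction settling at the final radius,
  since repulsion leaves points mid-oscillation;
* **sharpen** (2 iterations): each point is projected onto the principal
  line of its skeleton neighborhood (radius $1.2 r$), restricted to its
  constraint-plane slab when one is stored — kernel attraction contracts a
  flat cross-section only to a residual band, and the line projection
  collapses that band without eroding tips. A point whose neighborhood is
  ambiguous (slab holds a minority and the unfiltered neighborhood is not
  line-like) is left where the contraction put it;
* **merge**: points closer than $1.2\,r_0$ merge into their mean. Dense
  candidate sampling (`sample_fraction` 0.07) is needed so thin branches
  are covered without axial gaps, but over-close points amplify the
  edge-angle noise that the later split rule reacts to; merging restores
  an even spacing;
* **isolation filter**: points with no other skeleton point within 3x the
  median neighbor distance are contraction debris, not organ axes, and
  are dropped.

### Connection and its failure modes

DBSCAN uses `eps` of three median nearest-neighbor spacings and
`min_pts = 3`. Before clustering, two groups of skeleton points are set
aside: points with very low source support (thin pedicel wisps and debris,
below 15% of the median support) and points that fail a local
line-likelihood test (rms residual of the 0.6-eps neighborhood from its
principal line above 15% of that radius). The latter are the branch
junctions: keeping them would fuse several organs into one class and force
the path to zigzag through the junction. Removing them is the
"hierarchical" step — the skeleton decomposes into clean inter-junction
chains.

Within a class, growth starts at the point with maximal
directionality-weighted distance from the class centroid (a tip), and each
step attaches the nearest unconnected point whose direction has cosine
$> -0.25$ with the growing end's tangent. The threshold sits slightly
below zero on purpose: lateral jitter must not make the true next point
inadmissible, while genuine backtracking (the classic short-cut
misconnection) remains forbidden. If no admissible point remains, the
nearest one is attached regardless, so the polyline always visits the
whole class; implausibly long bridges created this way are severed later.
Interior vertices of each polyline get one pass of 1/4–1/2–1/4 smoothing:
a single noisy vertex otherwise reads as a sharp kink.

### Optimization rules

With $\bar d_{sk}$ the mean distance between connected skeleton points
(computed once per pass):

* **split**: every interior vertex whose two edges meet at $\le 165^\circ$
  severs the polyline (the kink vertex ends the left fragment);
* **cut**: edges of at least $5 \bar d_{sk}$ are severed (these are the
  connection fallback's bridges);
* **merge** (greedy, smallest gap first): two sub-skeletons concatenate
  when, for their nearest end pairing, the gap is $< 5 \bar d_{sk}$ and
  both angles between the outward end tangents and the connecting line are
  $< 15^\circ$.

The thresholds interlock: merging requires end angles strictly below
15°, which leaves every junction vertex angle strictly above 165°, so a
second pass never splits what the first pass merged — `optimize` is
idempotent, and it conserves the multiset of skeleton points.

### Trait extraction

Sub-skeletons longer than 200 mm are branches (strict inequality: exactly
200 mm remains a candidate). Because a stem crossing several junctions
emerges as a chain of collinear pieces, classification also considers
*chained length*: pieces whose ends face each other within 35 mm at under
20° collinearity (measured on multi-point end chords — single terminal
edges are too noisy) belong to one chain, and every member of a chain
longer than 200 mm counts as a branch piece. A second guard rejects
candidates whose cross-section is too thick to be a flat pod (median
smaller slab extent above 2.2 mm, between the pod thickness and the
thinnest branch diameter); thickness is measured on the raw radius
neighborhood, since the plane-constrained assignment would slice any tube
into a flat-looking slab.

Candidate tips are extended into the contiguous support of nearby source
points (lateral corridor 2.5 mm, step 2.5 mm, at most 12 mm and at most
35% of the piece's length per side): L1 contraction erodes tips, and the
proportional cap prevents a short stub from growing into a "silique" by
walking along its branch.

Effective siliques are selected by length: the mean $\mu$ comes from the
middle 60% of the sorted candidate lengths (ranks $\lfloor 0.2m\rfloor$ to
$\lfloor 0.8m\rfloor$, half-open — robust against leftover stem pieces), the
standard deviation $\sigma$ from all candidates, and a candidate is kept
when its length falls within $[\max(15\ \mathrm{mm},\ \mu - 1.96\sigma),\
\mu + 1.96\sigma]$ (a 95% population interval; the floor removes aborted
pods). The upper bound mirrors the lower one; the interval's printed form
in the underlying method repeats the lower expression, an evident typo.
$\sigma$ uses all candidates because the trimming rule is defined for the
mean only.

Per-silique volume accumulates slab-wise: skeleton point $A$ with
neighbors at distances $d_1$ (behind) and $d_2$ (ahead) owns the assigned
points whose *arc-length* coordinate (not the raw axial projection — this
handles curvature) lies in $[A - d_1/2,\ A + d_2/2]$; the slab's points
are projected on the plane normal to the local tangent, the projected
distribution is taken as a rectangle with robust 1st–99th percentile
extents $L \ge W$ along its 2D principal axes, and the slab contributes
$L\,W\,(d_1+d_2)/2$. End points use their single neighbor distance on the
existing side only; slabs with fewer than three points contribute nothing.
SN is the effective count; total SL and SV are sums over effective
siliques.

## The synthetic plant generator

`generate_plant()` builds labeled clouds with full ground truth, so every
stage is testable without scanned data. What it emulates:

* the three branch architectures (few-branch broom, multibranch broom,
  multibranch cylinder), with mean first/second/third branch counts of
  1/3.7/0.1, 1.3/6.3/4.3 and 4.2/14.2/6.2 respectively;
* siliques as flat boxes (3 × 1.5 mm cross-section, lengths
  N(60, 8²) mm truncated at 25 mm), attached by thin 10–18 mm pedicels at
  20–70° insertion angles, packed about every 10 mm on the terminal
  racemes of the branches — racemes fill one branch after another, so
  lower branch spans stay bare, as on real mature plants;
* an inverted-frustum pot (radii 40→60 mm over 100 mm height);
* per-organ sector occlusion (one contiguous third of each organ's
  circumference, emulating the partial horizontal coverage of a handheld
  scan) and Gaussian sensor noise of 0.05 mm;
* surface sampling at 1 point/mm².

The true volume of each synthetic silique is exactly cross-section area
times axis length — the analytic anchor for the volume tests.

What it does **not** emulate: leaves (mature plants are defoliated),
registration artifacts between partial scans, mixed per-region point
densities, silique curvature and tapering, and contact between touching
pods. Passing tests on generator clouds therefore demonstrate the
geometric correctness of the pipeline, not its robustness to every
artifact of real scans.

Problem sizes in the test-suite and acceptance runs are scaled down
(typically 20–40 siliques per plant at 1 point/mm²; real scans carry
hundreds of pods at far higher density). The silique-per-branch geometry —
raceme packing, pedicel lengths, organ separations — is kept realistic, so
the per-organ difficulty is representative even though plant-level totals
are smaller.

## Worked example

```{r example, eval = FALSE}
plant <- generate_plant(plant_spec(architecture = "FBBS",
                                   n_siliques = 30, seed = 101))
traits <- run_pipeline(plant$cloud, output_dir = "out")
traits
#> plant_traits: SN = 31 effective siliques (35 candidates, 5 branches)
#>   total SL = 1752.6 mm, total SV = 7263.4 mm^3
plant$truth$sn        # 30
plant$truth$total_sl  # 1781.4
```

## Known limitations

* Thin (< 3 mm) branches whose cross-section resembles a pod's can
  occasionally pass the flatness guard; short bare-branch pieces inside
  the silique length range are the dominant false-positive mode, so SN
  runs a few percent high on heavily branched architectures.
* The split rule cannot be undone by the merge rule (by design, for
  idempotence); a pod severed by a genuine kink in its skeleton stays two
  candidates unless one half falls outside the length interval.
* Noise beyond ~0.3 mm — several times the scanner resolution the method
  assumes — collapses detection, since pods are only 1.5 mm thick.
* Pot removal culls everything inside the fitted circles up to the pot
  height, including a stem passing through that region (documented
  collateral, matching the slab geometry of the approach).
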