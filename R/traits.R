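#' Polyline length of a sub-skeleton
#'
#' Sum of Euclidean distances between consecutive ordered skeleton points;
#' a single point has length 0.
#'
#' @param s a `sub_skeleton` (or n x 3 matrix of ordered points).
#' @return length in mm.
#' @export
subskeleton_length <- function(s) {
  p <- if (inherits(s, "sub_skeleton")) s$points else as.matrix(s)
  m <- nrow(p)
  if (m < 2) return(0)
  sum(.row_norms(p[-1, , drop = FALSE] - p[-m, , drop = FALSE]))
}

#' Separate branches from silique candidates
#'
#' Sub-skeletons longer than `branch_len_thresh` are stems/branches (95% of
#' sub-skeletons over 200 mm are long branches in mature oilseed rape); the
#' rest are silique candidates. The comparison is strict, so a sub-skeleton
#' of exactly the threshold length is a candidate.
#'
#' @param subskeletons list of `sub_skeleton`.
#' @param branch_len_thresh length cutoff in mm (default 200).
#' @return list with `branches` and `candidates` (lists of `sub_skeleton`),
#'   plus index vectors `branch_idx` / `candidate_idx` into the input.
#' @export
classify_branches <- function(subskeletons, branch_len_thresh = 200) {
  lens <- vapply(subskeletons, subskeleton_length, 0)
  bi <- which(lens > branch_len_thresh)
  ci <- which(lens <= branch_len_thresh)
  list(branches = subskeletons[bi], candidates = subskeletons[ci],
       branch_idx = bi, candidate_idx = ci, lengths = lens)
}

#' Effective-silique length filter
#'
#' Silique length is near-normally distributed within a plant. The mean is
#' estimated robustly from the middle 60% of the sorted candidate lengths
#' (ranks `int(0.2 m)` to `int(0.8 m)`, half-open), the standard deviation
#' from all candidates, and candidates are kept when their length falls in
#' `[max(floor_mm, mu - z * sigma), mu + z * sigma]` (bounds inclusive).
#' The floor removes aborted (stunted, seedless) siliques.
#'
#' @param candidate_lengths numeric vector of candidate lengths (mm),
#'   nonempty.
#' @param floor_mm abortion floor in mm (default 15).
#' @param z interval half-width in standard deviations (default 1.96, a 95%
#'   population interval).
#' @return list with `mu`, `sigma`, `lower`, `upper` and logical `keep`
#'   aligned to the input order.
#' @export
effective_filter <- function(candidate_lengths, floor_mm = 15, z = 1.96) {
  m <- length(candidate_lengths)
  if (m == 0) stop("effective_filter needs at least one candidate length")
  srt <- sort(candidate_lengths)
  i0 <- floor(0.2 * m) + 1
  i1 <- floor(0.8 * m)
  mu <- if (i1 >= i0) mean(srt[i0:i1]) else mean(srt)
  sigma <- if (m > 1) sd(candidate_lengths) else 0
  lower <- max(floor_mm, mu - z * sigma)
  upper <- mu + z * sigma
  keep <- candidate_lengths >= lower & candidate_lengths <= upper
  list(mu = mu, sigma = sigma, lower = lower, upper = upper, keep = keep)
}

#' Assign source points to sub-skeletons
#'
#' Each source point within `radius` of any skeleton point is assigned to
#' the nearest sub-skeleton (ties to the smaller sub-skeleton id), provided
#' it also lies within `T_d` of the local constraint plane at its nearest
#' skeleton point — the same plane-slab rule that guards the contraction.
#' Planes are RANSAC-fitted to the radius neighborhood of each skeleton
#' point; when a neighborhood is too small or degenerate the plane test is
#' waived for it. Assignments are disjoint across sub-skeletons.
#'
#' @param cloud the source [point_cloud()].
#' @param subskeletons one `sub_skeleton` or a list of them.
#' @param T_d plane slab half-thickness in mm (default 1.5).
#' @param radius search radius around skeleton points in mm (default 3).
#' @param seed seed for the plane fits (deterministic assignment).
#' @return an integer index vector (single sub-skeleton) or a list of
#'   disjoint index vectors (one per sub-skeleton).
#' @export
assign_silique_points <- function(cloud, subskeletons, T_d = 1.5, radius = 3,
                                  seed = 1) {
  single <- inherits(subskeletons, "sub_skeleton")
  subs <- if (single) list(subskeletons) else subskeletons
  nsub <- length(subs)
  out <- rep(list(integer(0)), nsub)
  if (n_points(cloud) == 0 || nsub == 0)
    return(if (single) out[[1]] else out)
  sizes <- vapply(subs, function(s) nrow(s$points), 0L)
  skel <- do.call(rbind, lapply(subs, `[[`, "points"))
  sub_of <- rep(seq_len(nsub), sizes)
  src <- cloud$points
  nb <- cpp_radius_neighbors(skel, src, radius)   # skeleton pts near each source pt
  cand <- which(lengths(nb) > 0)
  if (length(cand)) {
    # nearest skeleton point per source point; ties to the smaller sub id
    nearest <- vapply(cand, function(q) {
      js <- nb[[q]]
      d2 <- rowSums((skel[js, , drop = FALSE] -
                       matrix(src[q, ], length(js), 3, byrow = TRUE))^2)
      o <- order(d2, sub_of[js], js)
      js[o[1]]
    }, 0L)
    # one constraint plane per used skeleton point
    used <- sort(unique(nearest))
    planes <- with_local_seed(seed, {
      nbk <- cpp_radius_neighbors(src, skel[used, , drop = FALSE], radius)
      lapply(seq_along(used), function(t) {
        js <- nbk[[t]]
        if (length(js) < 3) return(NULL)
        P <- src[js, , drop = FALSE]
        if (nrow(P) > 150) P <- P[seq(1, nrow(P), length.out = 150), ,
                                  drop = FALSE]
        .ransac_fit(P, inlier_tol = min(0.5, T_d / 2), iters = 20,
                    anchor = skel[used[t], ], anchor_tol = T_d)
      })
    })
    plane_of <- match(nearest, used)
    ok <- vapply(seq_along(cand), function(t) {
      pl <- planes[[plane_of[t]]]
      if (is.null(pl)) return(TRUE)
      plane_distance(src[cand[t], , drop = FALSE], pl) < T_d
    }, TRUE)
    kept <- cand[ok]
    ksub <- sub_of[nearest[ok]]
    out <- lapply(seq_len(nsub), function(k) kept[ksub == k])
  }
  if (single) out[[1]] else out
}

#' Silique volume from slab-wise bounding rectangles
#'
#' Walks the sub-skeleton: every skeleton point `A` with neighbors at
#' arc-length distances `d1` (behind) and `d2` (ahead) owns the slab of
#' assigned points whose arc-length coordinate falls in
#' `[A - d1/2, A + d2/2]`. Slab points are projected on the plane normal to
#' the local tangent, the projected distribution is taken as rectangular
#' with extents `L >= W` along its 2D principal axes (robust 1st-99th
#' percentile extents), and the slab contributes `L * W * (d1 + d2) / 2`.
#' End points use their single neighbor distance on the existing side only.
#' Slabs with fewer than 3 points contribute 0.
#'
#' @param points assigned source points (matrix or indices are the caller's
#'   business; pass coordinates).
#' @param s a `sub_skeleton` with at least 2 points.
#' @param robust_q lower/upper quantiles of the projected extents
#'   (default `c(0.01, 0.99)`).
#' @return volume in mm^3.
#' @export
silique_volume <- function(points, s, robust_q = c(0.01, 0.99)) {
  st <- .slab_stats(points, s, robust_q)
  if (is.null(st)) return(0)
  sum(st$L * st$W * st$thickness)
}

# slab-wise projected rectangle statistics along a sub-skeleton: one row per
# skeleton point owning >= 3 assigned points (L >= W are the robust extents
# in the local normal plane; thickness is the slab's axial span)
.slab_stats <- function(points, s, robust_q = c(0.01, 0.99)) {
  p <- if (inherits(s, "sub_skeleton")) s$points else as.matrix(s)
  m <- nrow(p)
  if (m < 2) stop("slab statistics need a sub-skeleton with >= 2 points")
  pts <- as.matrix(points)
  if (nrow(pts) == 0) return(NULL)
  edge <- .row_norms(p[-1, , drop = FALSE] - p[-m, , drop = FALSE])
  arc <- c(0, cumsum(edge))
  # arc-length coordinate of each source point: nearest-segment projection
  t_best <- rep(NA_real_, nrow(pts))
  d_best <- rep(Inf, nrow(pts))
  for (seg in seq_len(m - 1)) {
    a <- p[seg, ]; bvec <- p[seg + 1, ] - a
    L2 <- sum(bvec^2)
    if (L2 < 1e-20) next
    rel <- sweep(pts, 2, a)
    tt <- pmin(pmax((rel %*% bvec)[, 1] / L2, 0), 1)
    proj <- outer(tt, bvec)
    d2 <- rowSums((rel - proj)^2)
    upd <- d2 < d_best
    d_best[upd] <- d2[upd]
    t_best[upd] <- arc[seg] + tt[upd] * sqrt(L2)
  }
  out <- data.frame(i = integer(0), L = numeric(0), W = numeric(0),
                    thickness = numeric(0), n = integer(0))
  for (i in seq_len(m)) {
    d1 <- if (i > 1) edge[i - 1] else 0
    d2 <- if (i < m) edge[i] else 0
    lo <- arc[i] - d1 / 2
    hi <- arc[i] + d2 / 2
    inslab <- t_best >= lo & (if (i < m) t_best < hi else t_best <= hi)
    if (sum(inslab) < 3) next
    v <- tangent_at(p, i)
    # orthonormal basis of the normal plane
    ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * v) * v
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(v[2] * e1[3] - v[3] * e1[2],
            v[3] * e1[1] - v[1] * e1[3],
            v[1] * e1[2] - v[2] * e1[1])
    rel <- sweep(pts[inslab, , drop = FALSE], 2, p[i, ])
    uv <- cbind(rel %*% e1, rel %*% e2)
    uv <- sweep(uv, 2, colMeans(uv))
    C <- crossprod(uv) / nrow(uv)
    ax <- eigen(C, symmetric = TRUE)$vectors
    prc <- uv %*% ax
    ext <- apply(prc, 2, function(w) diff(quantile(w, robust_q, names = FALSE)))
    out[nrow(out) + 1, ] <- c(i, max(ext), min(ext), (d1 + d2) / 2,
                              sum(inslab))
  }
  if (nrow(out) == 0) NULL else out
}

#' Cross-section thickness of a candidate
#'
#' Median over slabs of the smaller projected extent `W` — the thickness of
#' the organ around the sub-skeleton. Flat siliques have thickness close to
#' their pod thickness; stem pieces are round tubes and come out near their
#' diameter.
#'
#' @param points assigned source point coordinates.
#' @param s a `sub_skeleton` with at least 2 points.
#' @return thickness in mm (NA when no slab has enough points).
#' @export
candidate_thickness <- function(points, s) {
  st <- .slab_stats(points, s)
  if (is.null(st)) return(NA_real_)
  median(st$W)
}

#' Trait-extraction parameters
#'
#' @param branch_len_thresh branch/silique length cutoff in mm (default 200).
#' @param floor_mm silique abortion floor in mm (default 15).
#' @param z effective-interval half-width in SD units (default 1.96).
#' @param T_d plane slab half-thickness for point assignment (mm, default
#'   1.5).
#' @param assign_radius assignment search radius (mm, default 3).
#' @param extend_tips snap sub-skeleton ends outward to the support of their
#'   assigned points before measuring length (default TRUE; L1 contraction
#'   pulls tips slightly inward).
#' @param max_thickness candidates whose cross-section thickness (see
#'   [candidate_thickness()]) exceeds this are stem pieces, not flat
#'   siliques, and are excluded from the silique pool (mm; default 2.2,
#'   between the pod thickness and the thinnest branch diameter; NA
#'   disables the check).
#' @param chain_gap,chain_angle a stem crossing several junctions comes out
#'   of connection as a chain of collinear pieces; pieces whose ends face
#'   each other within `chain_gap` mm at under `chain_angle` degrees are
#'   chained, and every member of a chain longer than `branch_len_thresh`
#'   is classified as a branch piece rather than a silique candidate
#'   (defaults 35 mm / 20 degrees — junction removal carves voids of up
#'   to a few cluster radii into a stem, and the chain must bridge them;
#'   `chain_gap = 0` disables chaining).
#' @param seed seed for the deterministic plane fits.
#' @return list of class `trait_params`.
#' @export
trait_params <- function(branch_len_thresh = 200, floor_mm = 15, z = 1.96,
                         T_d = 1.5, assign_radius = 3, extend_tips = TRUE,
                         max_thickness = 2.2, chain_gap = 35, chain_angle = 20,
                         seed = 1) {
  structure(list(branch_len_thresh = branch_len_thresh, floor_mm = floor_mm,
                 z = z, T_d = T_d, assign_radius = assign_radius,
                 extend_tips = extend_tips, max_thickness = max_thickness,
                 chain_gap = chain_gap, chain_angle = chain_angle,
                 seed = seed),
            class = "trait_params")
}

# union-find chaining of collinear sub-skeletons: returns the summed length
# of each sub-skeleton's chain (members' lengths plus bridged gaps)
.chain_lengths <- function(subs, lens, max_gap, max_angle) {
  n <- length(subs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  gaps <- numeric(n)
  sizes <- vapply(subs, function(s) nrow(s$points), 0L)
  for (i in seq_len(n - 1)) {
    if (sizes[i] < 2) next
    pa <- subs[[i]]$points
    ea <- pa[c(1, sizes[i]), , drop = FALSE]
    for (j in (i + 1):n) {
      if (sizes[j] < 2) next
      pb <- subs[[j]]$points
      eb <- pb[c(1, sizes[j]), , drop = FALSE]
      combos <- expand.grid(ia = c(1L, sizes[i]), ib = c(1L, sizes[j]))
      gap <- sqrt(rowSums((pa[combos$ia, , drop = FALSE] -
                             pb[combos$ib, , drop = FALSE])^2))
      k <- which.min(gap)
      if (gap[k] >= max_gap) next
      # multi-point end chords: single terminal edges are too noisy to
      # judge collinearity across a gap
      end_dir <- function(p, e) {
        n <- nrow(p)
        inner <- if (e == 1) min(n, 4) else max(1, n - 3)
        v <- p[e, ] - p[inner, ]
        nv <- sqrt(sum(v^2))
        if (nv < 1e-12) NULL else v / nv
      }
      t_a <- end_dir(pa, combos$ia[k])
      t_b <- end_dir(pb, combos$ib[k])
      if (is.null(t_a) || is.null(t_b)) next
      conn <- pb[combos$ib[k], ] - pa[combos$ia[k], ]
      # collinearity of the two pieces (robust even when the short
      # connection line is laterally offset), plus a loose heading check
      g_tt <- .angle_deg(t_a, -t_b)
      g1 <- .angle_deg(t_a, conn)
      g2 <- .angle_deg(t_b, -conn)
      if (is.na(g_tt) || is.na(g1) || is.na(g2)) next
      if (g_tt >= max_angle || g1 >= 45 || g2 >= 45) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) {
        parent[rj] <- ri
        gaps[ri] <- gaps[ri] + gaps[rj] + gap[k]
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  tot <- tapply(lens, roots, sum)
  as.numeric(tot[as.character(roots)]) + gaps[roots]
}

# extend both polyline ends along their outward tangents into the
# contiguous support of nearby source points: the contraction erodes tips
# (and junction removal can erode bases), but the organ's own points mark
# how far it really reaches. The walk stops at the first axial gap larger
# than `step`, so the extension cannot jump onto a neighboring organ.
.extend_tips <- function(s, pts, lateral = 2.5, max_ext = 12, step = 2.5) {
  p <- s$points
  if (nrow(p) < 2 || nrow(pts) == 0) return(s)
  # proportional cap: a stub must not grow into a "silique" by walking
  # along the support of the branch it sits on
  max_ext <- min(max_ext, 0.35 * subskeleton_length(s))
  if (max_ext < 1e-6) return(s)
  for (side in c(1L, 2L)) {
    idx <- if (side == 1L) 1L else nrow(p)
    t_out <- tangent_at(p, idx)
    rel <- sweep(pts, 2, p[idx, ])
    proj <- (rel %*% t_out)[, 1]
    lat2 <- rowSums(rel^2) - proj^2
    sel <- proj > 0 & proj <= max_ext & lat2 < lateral^2
    if (!any(sel)) next
    ax <- sort(proj[sel])
    reach <- 0
    for (a in ax) {
      if (a - reach > step) break
      reach <- a
    }
    if (reach < 1e-6) next
    newp <- p[idx, ] + reach * t_out
    p <- if (side == 1L) rbind(newp, p) else rbind(p, newp)
  }
  new_sub_skeleton(p, class_id = s$class_id)
}

#' Plant-level silique traits
#'
#' Full hierarchical trait extraction: classify sub-skeletons into branches
#' and silique candidates, assign source points to the candidates, optionally
#' extend candidate tips to their point support, filter effective siliques by
#' the length interval, and accumulate per-silique volumes. `SN_E` is the
#' effective silique count; total SL/SV are sums over effective siliques.
#'
#' @param subskeletons list of `sub_skeleton` (after optimization).
#' @param cloud the source [point_cloud()].
#' @param params a [trait_params()].
#' @return object of class `plant_traits`: `sn_e`, `total_sl`, `total_sv`,
#'   per-silique table `siliques` (id, length_mm, volume_mm3, n_points,
#'   effective), `n_branches`, the filter summary, and the assigned point
#'   index sets.
#' @export
plant_traits <- function(subskeletons, cloud, params = trait_params()) {
  lens_all <- vapply(subskeletons, subskeleton_length, 0)
  chain <- if (params$chain_gap > 0 && length(subskeletons) > 1)
    .chain_lengths(subskeletons, lens_all, params$chain_gap,
                   params$chain_angle)
  else lens_all
  is_branch <- lens_all > params$branch_len_thresh |
    chain > params$branch_len_thresh
  cls <- list(branches = subskeletons[is_branch],
              candidates = subskeletons[!is_branch])
  cands <- cls$candidates
  if (length(cands) == 0) {
    return(structure(list(sn_e = 0L, total_sl = 0, total_sv = 0,
                          siliques = data.frame(id = integer(0),
                                                length_mm = numeric(0),
                                                volume_mm3 = numeric(0),
                                                n_points = integer(0),
                                                effective = logical(0)),
                          n_branches = length(cls$branches),
                          filter = NULL, assigned = list()),
                     class = "plant_traits"))
  }
  assigned <- assign_silique_points(cloud, cands, T_d = params$T_d,
                                    radius = params$assign_radius,
                                    seed = params$seed)
  if (params$extend_tips) {
    cands <- lapply(cands, .extend_tips, pts = cloud$points)
  }
  lens <- vapply(cands, subskeleton_length, 0)
  # flatness veto: stem pieces shorter than the branch cutoff are round and
  # thick in cross-section, unlike flat siliques. Thickness is measured on
  # the raw radius neighborhood — the plane-constrained assignment would
  # slice any tube down to a flat-looking slab.
  thick <- rep(NA_real_, length(cands))
  if (!is.na(params$max_thickness)) {
    thick <- vapply(seq_along(cands), function(k) {
      if (nrow(cands[[k]]$points) < 2) return(NA_real_)
      raw <- unique(unlist(cpp_radius_neighbors(
        cloud$points, cands[[k]]$points, params$assign_radius),
        use.names = FALSE))
      if (length(raw) < 3) return(NA_real_)
      candidate_thickness(cloud$points[raw, , drop = FALSE], cands[[k]])
    }, 0)
  }
  slim <- is.na(thick) | thick <= params$max_thickness
  eff <- rep(FALSE, length(cands))
  flt <- NULL
  if (any(slim)) {
    flt <- effective_filter(lens[slim], floor_mm = params$floor_mm,
                            z = params$z)
    eff[slim] <- flt$keep
  }
  vols <- numeric(length(cands))
  for (k in which(eff)) {
    pk <- cloud$points[assigned[[k]], , drop = FALSE]
    vols[k] <- if (nrow(pk) >= 3 && nrow(cands[[k]]$points) >= 2)
      silique_volume(pk, cands[[k]]) else 0
  }
  tab <- data.frame(id = seq_along(cands), length_mm = lens,
                    volume_mm3 = vols, thickness_mm = thick,
                    n_points = lengths(assigned), effective = eff)
  structure(list(sn_e = sum(eff), total_sl = sum(lens[eff]),
                 total_sv = sum(vols[eff]), siliques = tab,
                 n_branches = length(cls$branches), filter = flt,
                 assigned = assigned),
            class = "plant_traits")
}

#' @export
print.plant_traits <- function(x, ...) {
  cat(sprintf(paste0("plant_traits: SN = %d effective siliques ",
                     "(%d candidates, %d branches)\n",
                     "  total SL = %.1f mm, total SV = %.1f mm^3\n"),
              x$sn_e, nrow(x$siliques), x$n_branches, x$total_sl, x$total_sv))
  invisible(x)
}

#' Labeled cloud from assignments
#'
#' Builds a per-point label vector: effective siliques get their silique id,
#' everything else is -1.
#'
#' @param traits a `plant_traits`.
#' @param cloud the source [point_cloud()].
#' @return a `point_cloud` with labels.
#' @export
label_cloud <- function(traits, cloud) {
  lab <- rep(-1L, n_points(cloud))
  for (k in seq_along(traits$assigned)) {
    if (isTRUE(traits$siliques$effective[k]))
      lab[traits$assigned[[k]]] <- k
  }
  point_cloud(cloud$points, labels = lab, attrs = cloud$attrs)
}
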