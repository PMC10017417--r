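#' Skeleton optimization parameters
#'
#' @param merge_angle_max both end angles must be below this (degrees,
#'   default 15) for two sub-skeletons to merge.
#' @param merge_dist_factor end gap must be below this multiple of the mean
#'   connected-point distance (default 5).
#' @param split_angle_min interior points whose edge angle is at or below
#'   this (degrees, default 165) split the sub-skeleton.
#' @return list of class `optimize_params`.
#' @export
optimize_params <- function(merge_angle_max = 15, merge_dist_factor = 5,
                            split_angle_min = 165) {
  stopifnot(merge_angle_max > 0, merge_angle_max < split_angle_min,
            split_angle_min < 180, merge_dist_factor > 0)
  structure(list(merge_angle_max = merge_angle_max,
                 merge_dist_factor = merge_dist_factor,
                 split_angle_min = split_angle_min),
            class = "optimize_params")
}

#' Mean distance between connected skeleton points
#'
#' @param subskeletons list of `sub_skeleton`.
#' @return arithmetic mean of all consecutive-point distances (mm).
#' @export
mean_connected_distance <- function(subskeletons) {
  if (inherits(subskeletons, "sub_skeleton"))
    subskeletons <- list(subskeletons)
  lens <- unlist(lapply(subskeletons, function(s) {
    m <- nrow(s$points)
    if (m < 2) return(numeric(0))
    .row_norms(s$points[-1, , drop = FALSE] - s$points[-m, , drop = FALSE])
  }))
  if (length(lens) == 0) stop("no edges: every sub-skeleton is a single point")
  mean(lens)
}

# cut a polyline at every edge longer than maxlen
.cut_long_edges <- function(s, maxlen) {
  p <- s$points
  m <- nrow(p)
  if (m < 2) return(list(s))
  edge <- .row_norms(p[-1, , drop = FALSE] - p[-m, , drop = FALSE])
  cuts <- which(edge >= maxlen)
  if (length(cuts) == 0) return(list(s))
  starts <- c(1L, cuts + 1L)
  stops <- c(cuts, m)
  mapply(function(from, to)
    new_sub_skeleton(p[from:to, , drop = FALSE], class_id = s$class_id),
    starts, stops, SIMPLIFY = FALSE)
}

# angle in degrees between two vectors
.angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) return(NA_real_)
  cosang <- max(-1, min(1, sum(u * v) / (nu * nv)))
  acos(cosang) * 180 / pi
}

#' Try to merge two sub-skeletons
#'
#' A silique cut into two classes by clustering leaves two sub-skeletons
#' whose facing ends are close and nearly collinear. Among the four end-point
#' pairings the nearest one is evaluated: with `d_e` the end-to-end gap and
#' `g1`, `g2` the angles between each end's outward tangent and the
#' connecting line, the pieces are concatenated iff both angles are strictly
#' below `merge_angle_max` and `d_e` is strictly below
#' `merge_dist_factor * dsk_bar`.
#'
#' @param a,b `sub_skeleton` objects with at least 2 points each.
#' @param dsk_bar mean connected-point distance (mm), see
#'   [mean_connected_distance()].
#' @param params an [optimize_params()].
#' @return the merged `sub_skeleton`, or `NULL` when the rules do not fire.
#' @export
try_merge <- function(a, b, dsk_bar, params = optimize_params()) {
  pa <- a$points; pb <- b$points
  if (nrow(pa) < 2 || nrow(pb) < 2) return(NULL)
  na <- nrow(pa); nb <- nrow(pb)
  ends_a <- c(1L, na); ends_b <- c(1L, nb)
  combos <- expand.grid(ia = ends_a, ib = ends_b)
  gaps <- sqrt(rowSums((pa[combos$ia, , drop = FALSE] -
                        pb[combos$ib, , drop = FALSE])^2))
  k <- which.min(gaps)
  d_e <- gaps[k]
  ia <- combos$ia[k]; ib <- combos$ib[k]
  t_a <- tangent_at(pa, ia)            # outward at the chosen end
  t_b <- tangent_at(pb, ib)
  conn <- pb[ib, ] - pa[ia, ]
  g1 <- .angle_deg(t_a, conn)
  g2 <- .angle_deg(t_b, -conn)
  if (is.na(g1) || is.na(g2)) return(NULL)
  if (!(g1 < params$merge_angle_max && g2 < params$merge_angle_max &&
        d_e < params$merge_dist_factor * dsk_bar))
    return(NULL)
  # orient a to end at ia, b to start at ib, then concatenate
  qa <- if (ia == na) pa else pa[na:1, , drop = FALSE]
  qb <- if (ib == 1L) pb else pb[nb:1, , drop = FALSE]
  new_sub_skeleton(rbind(qa, qb), class_id = a$class_id)
}

#' Split a sub-skeleton at sharp interior points
#'
#' Two siliques fused into one class meet at a sharp kink. Every interior
#' point whose two incident edges meet at an angle at or below
#' `split_angle_min` degrees becomes a cut: the polyline is severed after
#' that point (the kink point ends the left fragment). Straight runs
#' (angles near 180) stay intact; fragments of one point are allowed.
#'
#' @param s a `sub_skeleton` with at least 3 points (fewer are returned
#'   unchanged).
#' @param params an [optimize_params()].
#' @return list of `sub_skeleton` fragments (length 1 when nothing splits).
#' @export
try_split <- function(s, params = optimize_params()) {
  p <- s$points
  m <- nrow(p)
  if (m < 3) return(list(s))
  ang <- vapply(2:(m - 1), function(i)
    .angle_deg(p[i - 1, ] - p[i, ], p[i + 1, ] - p[i, ]), 0)
  cuts <- which(ang <= params$split_angle_min) + 1L   # vertex indices
  if (length(cuts) == 0) return(list(s))
  starts <- c(1L, cuts + 1L)
  stops <- c(cuts, m)
  keep <- starts <= stops
  mapply(function(from, to)
    new_sub_skeleton(p[from:to, , drop = FALSE], class_id = s$class_id),
    starts[keep], stops[keep], SIMPLIFY = FALSE)
}

#' Optimize a set of sub-skeletons
#'
#' Applies [try_split()] to every sub-skeleton, computes the mean
#' connected-point distance once, and then greedily applies [try_merge()]
#' (smallest end gap first) over all pairs until no merge fires. The
#' multiset of skeleton points is conserved, and the result is a fixed
#' point: a second pass changes nothing, because merging requires end
#' angles strictly below `merge_angle_max`, which leaves every junction
#' angle strictly above `180 - merge_angle_max >= split_angle_min`.
#'
#' @param subskeletons list of `sub_skeleton`.
#' @param params an [optimize_params()].
#' @return list of `sub_skeleton`.
#' @export
optimize_subskeletons <- function(subskeletons, params = optimize_params()) {
  if (length(subskeletons) == 0) return(subskeletons)
  subs <- do.call(c, lapply(subskeletons, try_split, params = params))
  has_edge <- any(vapply(subs, function(s) nrow(s$points) >= 2, TRUE))
  if (!has_edge) return(subs)
  dsk_bar <- mean_connected_distance(subs)
  max_gap <- params$merge_dist_factor * dsk_bar
  # sever implausibly long edges (connection fallback can bridge distant
  # points to keep the path complete); the cut threshold equals the merge
  # distance limit, so severed pieces cannot immediately re-merge
  subs <- do.call(c, lapply(subs, .cut_long_edges, maxlen = max_gap))
  # evaluate one pair: smallest end gap if the merge rule fires, else NA
  eval_pair <- function(a, b) {
    na <- nrow(a$points); nb <- nrow(b$points)
    if (na < 2 || nb < 2) return(NA_real_)
    ea <- a$points[c(1, na), , drop = FALSE]
    eb <- b$points[c(1, nb), , drop = FALSE]
    gap <- min(sqrt(pmax(outer(rowSums(ea^2), rowSums(eb^2), "+") -
                           2 * tcrossprod(ea, eb), 0)))
    if (is.na(gap) || gap >= max_gap) return(NA_real_)
    if (is.null(try_merge(a, b, dsk_bar, params))) NA_real_ else gap
  }
  n <- length(subs)
  gapmat <- matrix(NA_real_, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        gapmat[i, j] <- eval_pair(subs[[i]], subs[[j]])
  }
  alive <- rep(TRUE, n)
  while (sum(alive) >= 2) {
    if (all(is.na(gapmat[alive, alive]))) break
    k <- which(gapmat == min(gapmat[alive, alive], na.rm = TRUE),
               arr.ind = TRUE)[1, ]
    i <- k[1]; j <- k[2]
    subs[[i]] <- try_merge(subs[[i]], subs[[j]], dsk_bar, params)
    alive[j] <- FALSE
    gapmat[j, ] <- NA; gapmat[, j] <- NA
    for (t in which(alive)) {
      if (t == i) next
      lo <- min(i, t); hi <- max(i, t)
      gapmat[lo, hi] <- eval_pair(subs[[lo]], subs[[hi]])
    }
  }
  subs[alive]
}
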