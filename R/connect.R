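#' DBSCAN clustering of skeleton points
#'
#' Standard density-based clustering: core points have at least `min_pts`
#' points (self included) within `eps`; classes are the connected components
#' of core points under eps-reachability, with border points attached to the
#' first core class that reaches them; the rest is noise. Noise points are
#' excluded from connection.
#'
#' @param skeleton a `skeleton_points` object or an n x 3 matrix.
#' @param eps reachability radius in mm; NULL = 3x the median
#'   nearest-neighbor spacing of the skeleton points.
#' @param min_pts minimum neighborhood size for a core point (default 3).
#' @return list with `classes` (list of index vectors), `noise` (index
#'   vector) and `labels` (integer vector, 0 = noise).
#' @export
cluster_skeleton <- function(skeleton, eps = NULL, min_pts = 3) {
  pts <- if (inherits(skeleton, "skeleton_points")) skeleton$positions
         else as.matrix(skeleton)
  n <- nrow(pts)
  if (n == 0)
    return(list(classes = list(), noise = integer(0), labels = integer(0)))
  if (is.null(eps)) {
    eps <- 3 * nn_spacing(pts, stat = median)
    if (!is.finite(eps) || eps <= 0) eps <- 1
  }
  stopifnot(eps > 0, min_pts >= 1)
  nb <- cpp_radius_neighbors(pts, pts, eps)
  core <- lengths(nb) >= min_pts
  labels <- integer(n)                 # 0 = unvisited/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier)) {
      reach <- unique(unlist(nb[frontier], use.names = FALSE))
      reach <- reach[labels[reach] == 0L]
      labels[reach] <- cl
      frontier <- reach[core[reach]]
    }
  }
  classes <- split(which(labels > 0L), labels[labels > 0L])
  names(classes) <- NULL
  list(classes = classes, noise = which(labels == 0L), labels = labels)
}

#' Tangent vector along an ordered polyline
#'
#' For an interior point the tangent is the chord direction from the previous
#' to the next point; for the first/last point it is the direction of the
#' terminal edge, oriented outward (past the end).
#'
#' @param points ordered n x 3 matrix (n >= 2).
#' @param i point index.
#' @return unit length-3 vector.
#' @export
tangent_at <- function(points, i) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("tangent undefined for an isolated point")
  v <- if (i == 1) points[1, ] - points[2, ]
       else if (i == n) points[n, ] - points[n - 1, ]
       else points[i + 1, ] - points[i - 1, ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("coincident neighbors give no tangent direction")
  v / nv
}

#' End-point test for an unordered class
#'
#' A point is an end point of the class's intrinsic order when all same-class
#' neighbors within 2x the median point spacing lie in one half-space of its
#' local principal direction.
#'
#' @param i index of the point within `class_points`.
#' @param class_points n x 3 matrix of the class (n >= 2).
#' @param spacing optional precomputed median nearest-neighbor spacing.
#' @return logical.
#' @export
is_end_point <- function(i, class_points, spacing = NULL) {
  pts <- as.matrix(class_points)
  n <- nrow(pts)
  if (n < 2) stop("end-point test needs a class of at least 2 points")
  if (is.null(spacing)) spacing <- nn_spacing(pts, stat = median)
  p <- pts[i, ]
  diffs <- sweep(pts[-i, , drop = FALSE], 2, p)
  d <- .row_norms(diffs)
  near <- diffs[d <= 2 * spacing & d > 0, , drop = FALSE]
  if (nrow(near) == 0) return(TRUE)
  dir <- eigen(crossprod(near), symmetric = TRUE)$vectors[, 1]
  s <- near %*% dir
  all(s > 0) || all(s < 0)
}

#' Connect one class of skeleton points into an ordered polyline
#'
#' Greedy growth with a direction-corrected nearest-neighbor search: the
#' initial point connects its nearest neighbor (if it is an end point) or its
#' two nearest neighbors; the path then grows from its two ends, each step
#' connecting the closest unconnected class point whose direction agrees with
#' the growing end's tangent (positive dot product; candidates behind the
#' search direction are inadmissible, the sign-flip of the weighted
#' unidirectional graph). Interior points end with exactly two incident
#' edges. Equal distances break toward the lowest point index. If no
#' admissible candidate remains while points are still unconnected, the
#' direction rule is relaxed for that step so the polyline visits every class
#' point exactly once.
#'
#' @param class_points n x 3 matrix (n >= 1).
#' @param seed seed for the random initial-point fallback.
#' @param lambda optional per-point directionality used to pick the initial
#'   point (maximal lambda-weighted distance from the class centroid —
#'   biased toward tips); NULL uses the distance alone.
#' @param init `"lambda"` (default) or `"random"` initial point choice.
#' @return object of class `sub_skeleton`: ordered `points`, `order` (the
#'   input indices in visiting order) and `class_id` (NA until assigned).
#' @export
connect_class <- function(class_points, seed = NULL, lambda = NULL,
                          init = c("lambda", "random")) {
  pts <- as.matrix(class_points)
  init <- match.arg(init)
  n <- nrow(pts)
  if (n == 1)
    return(new_sub_skeleton(pts, order = 1L))
  D <- as.matrix(dist(pts))
  diag(D) <- Inf
  if (init == "random") {
    i0 <- with_local_seed(seed, sample.int(n, 1))
  } else {
    ctr <- colMeans(pts)
    score <- .row_norms(sweep(pts, 2, ctr))
    if (!is.null(lambda)) score <- score * lambda
    i0 <- which.max(score)           # ties: first (lowest index)
  }
  spacing <- median(apply(D, 1, min))
  if (n == 2) {
    ord <- c(i0, setdiff(1:2, i0))
    return(new_sub_skeleton(pts[ord, , drop = FALSE], order = ord))
  }
  nn_order <- order(D[i0, ], seq_len(n))
  if (is_end_point(i0, pts, spacing)) {
    path <- c(i0, nn_order[1])
  } else {
    path <- c(nn_order[2], i0, nn_order[1])
  }
  used <- rep(FALSE, n)
  used[path] <- TRUE
  while (!all(used)) {
    free <- which(!used)
    ends <- c(path[1], path[length(path)])
    best <- NULL   # list(end_side, idx, dist)
    for (side in 1:2) {
      e <- ends[side]
      # outward tangent at this end of the current path
      epts <- pts[path, , drop = FALSE]
      t_out <- if (side == 1) tangent_at(epts, 1)
               else tangent_at(epts, nrow(epts))
      dirs <- sweep(pts[free, , drop = FALSE], 2, pts[e, ])
      dn <- pmax(.row_norms(dirs), 1e-12)
      # cosine threshold slightly below 0: lateral jitter must not make the
      # true next point inadmissible, while backtracking stays forbidden
      admissible <- (dirs %*% t_out)[, 1] / dn > -0.25
      cand <- free[admissible]
      if (length(cand) == 0) next
      dd <- D[e, cand]
      k <- order(dd, cand)[1]
      if (is.null(best) || dd[k] < best$dist ||
          (dd[k] == best$dist && cand[k] < best$idx)) {
        best <- list(side = side, idx = cand[k], dist = dd[k])
      }
    }
    if (is.null(best)) {
      # direction rule exhausted: fall back to plain nearest attachment
      d1 <- min(D[ends[1], free])
      d2 <- min(D[ends[2], free])
      side <- if (d1 <= d2) 1 else 2
      dd <- D[ends[side], free]
      best <- list(side = side, idx = free[order(dd, free)[1]],
                   dist = min(dd))
    }
    used[best$idx] <- TRUE
    path <- if (best$side == 1) c(best$idx, path) else c(path, best$idx)
  }
  new_sub_skeleton(pts[path, , drop = FALSE], order = path)
}

# internal sub-skeleton constructor
new_sub_skeleton <- function(points, order = NULL, class_id = NA_integer_) {
  points <- as.matrix(points)
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, order = order, class_id = class_id),
            class = "sub_skeleton")
}

#' @export
print.sub_skeleton <- function(x, ...) {
  cat(sprintf("sub_skeleton: %d points, length %.2f mm (class %s)\n",
              nrow(x$points), subskeleton_length(x), x$class_id))
  invisible(x)
}

#' Cluster and connect a skeleton into sub-skeletons
#'
#' Runs [cluster_skeleton()] and [connect_class()] over every class;
#' DBSCAN noise points are dropped.
#'
#' @param skeleton a `skeleton_points`.
#' @param eps,min_pts DBSCAN parameters (see [cluster_skeleton()]).
#' @param min_support_frac skeleton points whose source support is below
#'   this fraction of the median support are dropped before clustering
#'   (default 0.15): points contracted from a handful of source points
#'   (pedicel wisps, scan debris) carry no organ axis but bridge organs
#'   in the clustering.
#' @param drop_junctions drop skeleton points that do not sit on a locally
#'   line-like stretch before clustering (default TRUE). At branch
#'   junctions the neighborhood spans two axes; keeping those points makes
#'   one class span several organs and the connecting path zigzag through
#'   the junction. Removing them segments the skeleton into clean
#'   inter-junction chains — the hierarchical step of the segmentation.
#' @param junction_resid_frac residual threshold for the junction test, as
#'   a fraction of eps: a point is dropped when the rms distance of its
#'   eps-neighbors from their principal line exceeds this (default 0.15).
#' @param smooth_passes light 3-point smoothing passes (weights 1/4, 1/2,
#'   1/4) applied to interior vertices of each connected polyline (default
#'   1). A single noisy vertex otherwise reads as a sharp kink to the
#'   downstream edge-angle rules; genuine corners survive the smoothing
#'   well below the split threshold.
#' @param seed seed for random initial points (only used with
#'   `init = "random"`).
#' @param init initial-point rule, see [connect_class()].
#' @return list of `sub_skeleton` objects, `class_id` set from the DBSCAN
#'   class.
#' @export
connect_skeleton <- function(skeleton, eps = NULL, min_pts = 3,
                             min_support_frac = 0.15,
                             drop_junctions = TRUE,
                             junction_resid_frac = 0.15,
                             smooth_passes = 1, seed = NULL,
                             init = "lambda") {
  pts <- if (inherits(skeleton, "skeleton_points")) skeleton$positions
         else as.matrix(skeleton)
  lam <- if (inherits(skeleton, "skeleton_points")) skeleton$lambda
  sup <- if (inherits(skeleton, "skeleton_points")) skeleton$support
  if (!is.null(sup) && min_support_frac > 0 && length(sup) > 0) {
    keep <- sup >= min_support_frac * median(sup)
    pts <- pts[keep, , drop = FALSE]
    if (!is.null(lam)) lam <- lam[keep]
  }
  if (is.null(eps) && nrow(pts) >= 2) {
    eps <- 3 * nn_spacing(pts, stat = median)
    if (!is.finite(eps) || eps <= 0) eps <- 1
  }
  if (isTRUE(drop_junctions) && nrow(pts) >= 4) {
    # test radius below eps: the excluded zone around a junction must stay
    # narrow enough for the merge rule to reconnect the straight chains on
    # either side of it
    jrad <- 0.6 * eps
    nb <- cpp_radius_neighbors(pts, pts, jrad)
    resid <- vapply(seq_len(nrow(pts)), function(i) {
      idx <- nb[[i]]
      if (length(idx) < 4) return(0)
      Q <- pts[idx, , drop = FALSE]
      ctr <- colMeans(Q)
      Qc <- sweep(Q, 2, ctr)
      v <- eigen(crossprod(Qc), symmetric = TRUE)$vectors[, 1]
      perp2 <- rowSums(Qc^2) - (Qc %*% v)[, 1]^2
      sqrt(mean(pmax(perp2, 0)))
    }, 0)
    keep <- resid <= junction_resid_frac * jrad
    pts <- pts[keep, , drop = FALSE]
    if (!is.null(lam)) lam <- lam[keep]
  }
  cl <- cluster_skeleton(pts, eps = eps, min_pts = min_pts)
  out <- vector("list", length(cl$classes))
  for (k in seq_along(cl$classes)) {
    idx <- cl$classes[[k]]
    s <- connect_class(pts[idx, , drop = FALSE], seed = seed,
                       lambda = if (!is.null(lam)) lam[idx], init = init)
    for (sp in seq_len(smooth_passes)) {
      m <- nrow(s$points)
      if (m >= 3) {
        p <- s$points
        s$points[2:(m - 1), ] <-
          0.25 * p[1:(m - 2), ] + 0.5 * p[2:(m - 1), ] +
          0.25 * p[3:m, ]
      }
    }
    s$class_id <- k
    out[[k]] <- s
  }
  out
}

#' Write sub-skeletons as an edge-list CSV
#' @param subskeletons list of `sub_skeleton`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_subskeletons_csv <- function(subskeletons, path) {
  rows <- lapply(subskeletons, function(s) {
    m <- nrow(s$points)
    if (m < 2) return(NULL)
    data.frame(class_id = s$class_id,
               i = seq_len(m - 1), xi = s$points[-m, 1],
               yi = s$points[-m, 2], zi = s$points[-m, 3],
               j = 2:m, xj = s$points[-1, 1], yj = s$points[-1, 2],
               zj = s$points[-1, 3])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write sub-skeletons as OBJ line elements
#' @param subskeletons list of `sub_skeleton`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_subskeletons_obj <- function(subskeletons, path) {
  lines <- character(0)
  off <- 0L
  for (s in subskeletons) {
    m <- nrow(s$points)
    lines <- c(lines,
               sprintf("v %.6f %.6f %.6f", s$points[, 1], s$points[, 2],
                       s$points[, 3]),
               if (m >= 2) paste("l", paste(off + seq_len(m), collapse = " ")))
    off <- off + m
  }
  writeLines(lines, path)
  invisible(path)
}
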