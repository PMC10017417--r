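#' Gaussian neighborhood kernel
#'
#' Smoothly down-weights distant neighbors: `theta(d) = exp(-d^2 / (bw/2)^2)`,
#' where `bw` is the support scale (here the current neighborhood radius).
#'
#' @param d distances (mm).
#' @param bw kernel support scale (mm).
#' @return weights in (0, 1].
#' @export
theta_kernel <- function(d, bw) exp(-(d * d) / (bw / 2)^2)

#' Weighted L1-median of a point set
#'
#' Iterates the weighted-average fixed point `x <- sum(p_j w_j) / sum(w_j)`
#' with `w_j = theta(|x - p_j|) / |x - p_j|`. With a bandwidth much larger
#' than the point spread the kernel is flat and the fixed point is the
#' geometric median (the minimizer of the summed Euclidean distances); a
#' local bandwidth yields the locally weighted median used for skeleton
#' contraction. Distances are floored at 1e-8 mm so an iterate sitting on a
#' data point is handled.
#'
#' @param points numeric matrix (n x 3), nonempty.
#' @param init starting point; defaults to the centroid.
#' @param bandwidth kernel scale in mm (> 0).
#' @param max_iters iteration cap.
#' @param tol movement convergence threshold in mm.
#' @return the fixed-point location (length-3 vector).
#' @export
l1_median <- function(points, init = NULL, bandwidth = NULL,
                      max_iters = 200, tol = 1e-9) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("l1_median needs a nonempty point set")
  if (nrow(points) == 1) return(as.numeric(points[1, ]))
  if (is.null(bandwidth)) {
    spread <- max(apply(points, 2, function(v) diff(range(v))))
    bandwidth <- max(spread, 1) * 1e4   # effectively unweighted
  }
  x <- if (is.null(init)) colMeans(points) else as.numeric(init)
  for (it in seq_len(max_iters)) {
    diffs <- sweep(points, 2, x)
    d <- pmax(sqrt(rowSums(diffs * diffs)), .EPS_DIST)
    w <- theta_kernel(d, bandwidth) / d
    x_new <- colSums(points * w) / sum(w)
    if (sqrt(sum((x_new - x)^2)) < tol) { x <- x_new; break }
    x <- x_new
  }
  as.numeric(x)
}

#' Construct a plane
#' @param normal plane normal (will be normalized).
#' @param offset scalar `d` such that `normal . x + d = 0` on the plane.
#' @return object of class `plane3`.
#' @export
plane3 <- function(normal, offset) {
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("zero-length plane normal")
  structure(list(normal = as.numeric(normal) / nn,
                 offset = as.numeric(offset) / nn),
            class = "plane3")
}

#' Point-to-plane distances
#' @param points n x 3 matrix.
#' @param plane a `plane3`.
#' @return nonnegative distances (mm).
#' @export
plane_distance <- function(points, plane) {
  points <- as.matrix(points)
  abs(points %*% plane$normal + plane$offset)[, 1]
}

# RANSAC plane core: draws from the *current* RNG stream (callers that need
# determinism wrap it with with_local_seed). Returns NULL if every sample is
# degenerate (collinear points). With an `anchor`, only candidate planes
# passing within `anchor_tol` of that point compete for inliers — the
# constraint plane must run through the organ the anchor sits on, not a
# neighbor caught in the search radius.
.ransac_fit <- function(P, inlier_tol, iters, refine = TRUE,
                        anchor = NULL, anchor_tol = Inf, weights = NULL) {
  n <- nrow(P)
  idx <- matrix(sample.int(n, 3L * iters, replace = TRUE), iters, 3)
  p1 <- P[idx[, 1], , drop = FALSE]
  v1 <- P[idx[, 2], , drop = FALSE] - p1
  v2 <- P[idx[, 3], , drop = FALSE] - p1
  nx <- v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]
  ny <- v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3]
  nz <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  scale <- max(.row_norms(v1), .row_norms(v2), 1e-12)
  ok <- nrm > 1e-10 * scale
  if (!any(ok)) return(NULL)
  N <- cbind(nx, ny, nz)[ok, , drop = FALSE] / nrm[ok]
  offs <- -rowSums(N * p1[ok, , drop = FALSE])
  if (!is.null(anchor)) {
    near <- abs(N %*% as.numeric(anchor) + offs)[, 1] < anchor_tol
    if (any(near)) {
      N <- N[near, , drop = FALSE]
      offs <- offs[near]
    }
  }
  D <- abs(P %*% t(N) + rep(offs, each = n))
  # optional per-point weights (e.g. the contraction kernel): the winning
  # plane is the one explaining the *near* neighborhood, not any large
  # structure the search radius happens to intersect
  counts <- if (is.null(weights)) colSums(D < inlier_tol)
            else crossprod(weights, D < inlier_tol)[1, ]
  best <- which.max(counts)
  normal <- N[best, ]
  offset <- offs[best]
  if (refine) {
    inl <- which(D[, best] < inlier_tol)
    if (length(inl) >= 3) {
      Q <- P[inl, , drop = FALSE]
      ctr <- colMeans(Q)
      C <- crossprod(sweep(Q, 2, ctr)) / length(inl)
      ev <- eigen(C, symmetric = TRUE)
      cand <- ev$vectors[, 3]
      if (ev$values[2] > 1e-14 * max(ev$values[1], 1e-300)) {
        normal <- cand
        offset <- -sum(normal * ctr)
      }
    }
  }
  plane3(normal, offset)
}

#' RANSAC plane detection
#'
#' Fits the plane maximizing the inlier count at `inlier_tol` over `iters`
#' random 3-point samples, then (optionally) refines it by total least
#' squares on the inliers. Deterministic for a fixed `seed`.
#'
#' @param points n x 3 matrix, n >= 3.
#' @param inlier_tol inlier distance threshold in mm.
#' @param iters number of random samples.
#' @param seed integer seed (NULL uses, and advances, the caller's RNG).
#' @param refine refit on inliers (default TRUE).
#' @return a [plane3()].
#' @export
ransac_plane <- function(points, inlier_tol = 0.5, iters = 100, seed = NULL,
                         refine = TRUE) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("plane fit needs at least 3 points")
  fit <- with_local_seed(seed, .ransac_fit(points, inlier_tol, iters, refine))
  if (is.null(fit))
    stop("degenerate geometry: points are collinear, no plane found")
  fit
}

#' Restrict neighborhoods to a plane slab
#'
#' Keeps only the points whose distance to the constraint plane is strictly
#' below `T_d` — the guard that stops a growing neighborhood from absorbing
#' points of a different organ.
#'
#' @param J source-point neighborhood (matrix).
#' @param I skeleton-point neighborhood (matrix).
#' @param plane a [plane3()].
#' @param T_d distance threshold in mm.
#' @return list with constrained matrices `J` and `I`.
#' @export
constrain_neighborhood <- function(J, I, plane, T_d) {
  J <- as.matrix(J); I <- as.matrix(I)
  keep_j <- if (nrow(J)) plane_distance(J, plane) < T_d else logical(0)
  keep_i <- if (nrow(I)) plane_distance(I, plane) < T_d else logical(0)
  list(J = J[keep_j, , drop = FALSE], I = I[keep_i, , drop = FALSE])
}

#' Directionality degree of a neighborhood
#'
#' The fraction of local variance along the principal direction:
#' `lambda = s1 / (s1 + s2 + s3)` with `s1 >= s2 >= s3` the eigenvalues of
#' the (kernel-weighted) covariance of the neighbors about the point.
#' Collinear neighborhoods give 1, planar disks about 1/2, isotropic
#' (spherical) neighborhoods about 1/3. Zero neighbors give 0.
#'
#' @param point center (length-3).
#' @param neighbors matrix of neighbor coordinates.
#' @param bandwidth optional kernel scale; NULL weights all neighbors equally.
#' @return lambda in `[0, 1]`.
#' @export
directionality <- function(point, neighbors, bandwidth = NULL) {
  neighbors <- as.matrix(neighbors)
  if (nrow(neighbors) == 0) return(0)
  diffs <- sweep(neighbors, 2, as.numeric(point))
  w <- if (is.null(bandwidth)) rep(1, nrow(diffs))
       else theta_kernel(.row_norms(diffs), bandwidth)
  C <- crossprod(diffs * sqrt(w)) / sum(w)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  tot <- sum(ev)
  if (tot <= 1e-300) return(0)
  max(0, min(1, ev[1] / tot))
}

# keep only the slab points connected to `x` through links of length
# `link`: single-linkage component over the union of x, J and I
.connected_slab <- function(x, J, I, link) {
  nj <- nrow(J); ni <- nrow(I)
  if (nj + ni == 0) return(list(J = J, I = I))
  S <- rbind(matrix(x, 1, 3), J, I)
  nb <- cpp_radius_neighbors(S, S, link)
  inc <- logical(nrow(S))
  inc[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    reach <- unique(unlist(nb[frontier], use.names = FALSE))
    reach <- reach[!inc[reach]]
    inc[reach] <- TRUE
    frontier <- reach
  }
  list(J = J[inc[1 + seq_len(nj)], , drop = FALSE],
       I = I[inc[1 + nj + seq_len(ni)], , drop = FALSE])
}

#' Skeletonization parameters
#'
#' @param r0 initial neighborhood radius in mm; NULL = 2x the mean
#'   nearest-neighbor spacing of the (downsampled) cloud.
#' @param radius_growth radius increment per outer iteration, as a fraction
#'   of `r0` (default 0.5).
#' @param r_final target neighborhood radius in mm at the end of the
#'   growth schedule (default 5): the contraction engages only once the
#'   radius wraps an organ's cross-section, so the final radius must be an
#'   organ-scale length, independent of sampling density.
#' @param max_outer_iters outer iteration count; NULL (default) derives it
#'   from the schedule so the radius reaches `r_final` (at most 40).
#' @param min_outer_iters iterations run before the movement test applies
#'   (NULL, the default, runs the full radius schedule: before the radius
#'   wraps an organ's cross-section the contraction has not engaged and
#'   the movement is spuriously small, so an early exit is only safe when
#'   configured deliberately).
#' @param polish_iters pure-attraction settling iterations at the final
#'   radius after the main loop (default 3): repulsion regularizes spacing
#'   but leaves points mid-oscillation, and the downstream edge-angle rules
#'   need laterally smooth polylines.
#' @param sharpen_iters final passes that project every skeleton point onto
#'   the principal line of its skeleton neighborhood (default 2). Kernel
#'   attraction contracts a flat cross-section only down to a residual band;
#'   the line projection collapses that band without eroding the tips.
#' @param sharpen_radius_factor neighborhood radius of the line projection
#'   relative to the final contraction radius (default 1.2; smaller values
#'   under-smooth because too few points support each local line fit).
#' @param merge_radius skeleton points closer than this merge into their
#'   mean after contraction (NULL = 1.2 r0). Merging evens out the axial
#'   spacing: dense sampling is needed so thin branches stay covered, but
#'   over-close points amplify edge-angle noise downstream, and the merged
#'   means are laterally smoother than the raw points.
#' @param inner_tol mean-movement convergence threshold in mm (default 0.01).
#' @param tau attraction/repulsion balance (default 0.35).
#' @param kernel_bandwidth_factor kernel support relative to the current
#'   radius (default 1).
#' @param T_d plane slab half-thickness in mm (default 1.5; must exceed the
#'   silique half-thickness but stay below inter-silique gaps).
#' @param link_radius connectivity radius of the component filter in mm
#'   (default 2, above the organ thickness and below inter-organ gaps):
#'   after the plane-slab restriction, only the points connected to the
#'   candidate through links of this length remain. A plane can slice
#'   through several organs at once; connectivity keeps exactly the
#'   candidate's own.
#' @param flat_ratio_max flatness gate (default 0.08): the slab applies
#'   only while its connected content is genuinely flat (smallest
#'   covariance eigenvalue below this fraction of the total). A flat
#'   silique stays below the gate at every radius; a stem's connected
#'   shell exceeds it once the radius wraps the tube, releasing the
#'   constraint so the round cross-section can contract to its axis.
#' @param ransac_iters RANSAC samples per plane fit (default 20).
#' @param ransac_inlier_tol RANSAC inlier threshold in mm (default 1: it
#'   must cover the organ half-thickness so the refined plane tracks the
#'   mid-surface of a flat silique rather than one face).
#' @param sample_fraction fraction of source points seeded as skeleton
#'   candidates (default 0.07; thin branches need enough axial coverage
#'   that sampling gaps stay below the clustering reach).
#' @param max_points voxel-downsample the source to at most this many points
#'   before contraction (default 50000).
#' @param constrain apply the RANSAC plane constraint (default TRUE).
#' @param seed integer seed driving candidate sampling and RANSAC.
#' @return list of class `skeleton_params`.
#' @export
skeleton_params <- function(r0 = NULL, radius_growth = 0.5, r_final = 5,
                            max_outer_iters = NULL, min_outer_iters = NULL,
                            polish_iters = 3, sharpen_iters = 2,
                            sharpen_radius_factor = 1.2,
                            merge_radius = NULL, inner_tol = 0.01,
                            tau = 0.35, kernel_bandwidth_factor = 1.0,
                            T_d = 1.5, link_radius = 2,
                            flat_ratio_max = 0.08, ransac_iters = 20,
                            ransac_inlier_tol = 1.0, sample_fraction = 0.07,
                            max_points = 50000, constrain = TRUE, seed = 1) {
  stopifnot(is.null(r0) || r0 > 0, tau >= 0, sample_fraction > 0,
            sample_fraction <= 1, T_d > 0, radius_growth > 0,
            is.null(min_outer_iters) || min_outer_iters >= 1, r_final > 0)
  structure(list(r0 = r0, radius_growth = radius_growth, r_final = r_final,
                 max_outer_iters = max_outer_iters,
                 min_outer_iters = min_outer_iters,
                 polish_iters = polish_iters, sharpen_iters = sharpen_iters,
                 sharpen_radius_factor = sharpen_radius_factor,
                 merge_radius = merge_radius, inner_tol = inner_tol,
                 tau = tau, kernel_bandwidth_factor = kernel_bandwidth_factor,
                 T_d = T_d, link_radius = link_radius,
                 flat_ratio_max = flat_ratio_max,
                 ransac_iters = ransac_iters,
                 ransac_inlier_tol = ransac_inlier_tol,
                 sample_fraction = sample_fraction, max_points = max_points,
                 constrain = constrain, seed = seed),
            class = "skeleton_params")
}

#' L1-median skeleton extraction
#'
#' Contracts the cloud to skeleton points: candidates seeded by random
#' subsample move each outer iteration to a balance of attraction toward the
#' weighted L1-median of their source neighborhood and kernel-weighted
#' repulsion from neighboring candidates (strength `tau * lambda`, with
#' `lambda` the directionality of the candidate neighborhood). Before each
#' update the neighborhood is restricted to a RANSAC-fitted plane slab of
#' half-thickness `T_d`, which keeps flat elongate organs (siliques) from
#' contaminating each other as the radius grows. The neighborhood radius
#' starts at `r0` and grows by `radius_growth * r0` per iteration; iteration
#' stops when the mean candidate movement falls below `inner_tol` or after
#' `max_outer_iters` iterations. Deterministic for a fixed seed.
#'
#' @param cloud a nonempty [point_cloud()] (pot and noise already removed).
#' @param params a [skeleton_params()].
#' @return object of class `skeleton_points`: `positions`, per-point
#'   `lambda`, `radius`, `planes` (list of [plane3()] or NULL), the source
#'   indices of the seeds, and `spacing` (mean nearest-neighbor spacing).
#' @export
extract_skeleton <- function(cloud, params = skeleton_params()) {
  if (n_points(cloud) == 0) stop("cannot skeletonize an empty cloud")
  work <- cloud
  if (n_points(work) > params$max_points) {
    # grow the voxel until the budget is met
    voxel <- nn_spacing(work$points) %||% 1
    voxel <- max(voxel, 1e-6)
    repeat {
      ds <- voxel_downsample(work, voxel)
      if (n_points(ds) <= params$max_points) { work <- ds; break }
      voxel <- voxel * 1.3
    }
  }
  src <- work$points
  n <- nrow(src)
  spacing <- if (n >= 2) nn_spacing(src) else 1
  r0 <- params$r0 %||% (2 * spacing)
  n_iters <- params$max_outer_iters %||%
    min(40L, max(3L, ceiling((params$r_final / r0 - 1) /
                               params$radius_growth) + 1L))
  m <- max(1L, ceiling(params$sample_fraction * n))

  with_local_seed(params$seed, {
    seed_idx <- sort(sample.int(n, m))
    X <- src[seed_idx, , drop = FALSE]
    lambda <- numeric(m)
    support <- numeric(m)    # source points feeding the final update
    planes <- vector("list", m)
    r <- r0
    movement_trace <- numeric(0)

    # one contraction pass over all candidates at radius r and repulsion tau
    pass <- function(X, r, tau) {
      bw <- params$kernel_bandwidth_factor * r
      nb_src <- cpp_radius_neighbors(src, X, r)
      nb_skel <- cpp_radius_neighbors(X, X, r)
      X_new <- X
      moved <- numeric(m)
      for (i in seq_len(m)) {
        x <- X[i, ]
        jdx <- nb_src[[i]]
        if (length(jdx) < 3) next
        J <- src[jdx, , drop = FALSE]
        idx_i <- setdiff(nb_skel[[i]], i)
        I <- X[idx_i, , drop = FALSE]
        if (params$constrain) {
          # the "interferential points from other objects" are the ones
          # not connected to the candidate: restrict the neighborhood to
          # the candidate's connected component first
          conn <- .connected_slab(x, J, I, params$link_radius)
          if (nrow(conn$J) >= 3) {
            J <- conn$J
            I <- conn$I
            ev <- eigen(crossprod(sweep(J, 2, colMeans(J))),
                        symmetric = TRUE, only.values = TRUE)$values
            flat <- ev[3] / max(sum(ev), 1e-300) <= params$flat_ratio_max
            planes[i] <<- list(NULL)
            if (flat) {
              # the component is a flat organ: fit its plane and keep the
              # slab, which prunes whatever still hangs on at the fringes
              Jfit <- if (nrow(J) > 150)
                J[seq(1, nrow(J), length.out = 150), , drop = FALSE] else J
              pl <- .ransac_fit(Jfit, params$ransac_inlier_tol,
                                params$ransac_iters)
              if (!is.null(pl)) {
                cons <- constrain_neighborhood(J, I, pl, params$T_d)
                if (nrow(cons$J) >= 3) {
                  J <- cons$J
                  I <- cons$I
                  planes[[i]] <<- pl
                }
              }
            }
          }
        }
        dJ <- pmax(.row_norms(sweep(J, 2, x)), .EPS_DIST)
        alpha <- theta_kernel(dJ, bw) / dJ
        x_attr <- colSums(J * alpha) / sum(alpha)
        lam <- 0
        x_rep <- c(0, 0, 0)
        if (nrow(I) > 0) {
          diffs_i <- sweep(I, 2, x)
          dI <- pmax(.row_norms(diffs_i), .EPS_DIST)
          beta <- theta_kernel(dI, bw) / (dI * dI)
          lam <- directionality(x, I, bw)
          x_rep <- tau * lam * colSums(-diffs_i * beta) / sum(beta)
        }
        x_new <- x_attr + x_rep
        moved[i] <- sqrt(sum((x_new - x)^2))
        X_new[i, ] <- x_new
        lambda[i] <<- lam
      }
      list(X = X_new, moved = moved)
    }

    for (it in seq_len(n_iters)) {
      if (it == min(3L, n_iters)) {
        # support measured while the radius is still organ-scale: thin
        # wisps (pedicels, debris) have little source backing at this scale
        support <- lengths(cpp_radius_neighbors(src, X, r))
      }
      res <- pass(X, r, params$tau)
      X <- res$X
      movement_trace <- c(movement_trace, mean(res$moved))
      min_it <- params$min_outer_iters %||% n_iters
      if (it >= min_it && mean(res$moved) < params$inner_tol)
        break
      r <- r + params$radius_growth * r0
    }
    for (it in seq_len(params$polish_iters)) {
      X <- pass(X, r, 0)$X
    }
    for (it in seq_len(params$sharpen_iters)) {
      nbX <- cpp_radius_neighbors(X, X, params$sharpen_radius_factor * r)
      X_proj <- X
      for (i in seq_len(m)) {
        idx <- nbX[[i]]
        if (length(idx) < 3) next
        Q <- X[idx, , drop = FALSE]
        # the local line must belong to this point's organ: restrict to
        # the constraint plane slab, like the contraction itself. When the
        # slab keeps only a minority (e.g. a stale plane on a straggler),
        # project anyway if the unfiltered neighborhood is itself tightly
        # line-like; skip when it is ambiguous (two parallel organs in one
        # neighborhood — an unfiltered projection would land between them).
        ctr <- colMeans(Q)
        Qc <- sweep(Q, 2, ctr)
        v <- eigen(crossprod(Qc), symmetric = TRUE)$vectors[, 1]
        rms <- sqrt(mean(pmax(rowSums(Qc^2) - (Qc %*% v)[, 1]^2, 0)))
        if (params$constrain && !is.null(planes[[i]])) {
          keep <- plane_distance(Q, planes[[i]]) < params$T_d
          if (sum(keep) >= 3 && sum(keep) >= 0.5 * nrow(Q)) {
            Qk <- Q[keep, , drop = FALSE]
            ctr <- colMeans(Qk)
            Qc <- sweep(Qk, 2, ctr)
            v <- eigen(crossprod(Qc), symmetric = TRUE)$vectors[, 1]
          } else if (rms >= params$T_d / 3) next
        }
        X_proj[i, ] <- ctr + sum((X[i, ] - ctr) * v) * v
      }
      X <- X_proj
    }
    # merge near-coincident skeleton points (greedy, by ascending index)
    mrad <- params$merge_radius %||% (1.2 * r0)
    if (mrad > 0 && m > 1) {
      nbm <- cpp_radius_neighbors(X, X, mrad)
      taken <- rep(FALSE, m)
      keep_pos <- list(); keep_lam <- numeric(0); keep_pl <- list()
      keep_seed <- integer(0); keep_sup <- numeric(0)
      for (i in seq_len(m)) {
        if (taken[i]) next
        grp <- nbm[[i]][!taken[nbm[[i]]]]
        taken[grp] <- TRUE
        keep_pos[[length(keep_pos) + 1]] <-
          colMeans(X[grp, , drop = FALSE])
        keep_lam <- c(keep_lam, mean(lambda[grp]))
        keep_sup <- c(keep_sup, mean(support[grp]))
        keep_pl[[length(keep_pl) + 1]] <- planes[[i]]
        keep_seed <- c(keep_seed, seed_idx[i])
      }
      X <- do.call(rbind, keep_pos)
      lambda <- keep_lam
      support <- keep_sup
      planes <- keep_pl
      seed_idx <- keep_seed
      m <- nrow(X)
    }
    # isolated leftovers (no chain within 3x the median neighbor distance)
    # are contraction debris, not organ axes
    if (m >= 3) {
      d1 <- cpp_knn_dist(X, X, 1L, TRUE)[, 1]
      keep <- d1 <= 3 * median(d1)
      if (!all(keep)) {
        X <- X[keep, , drop = FALSE]
        lambda <- lambda[keep]
        support <- support[keep]
        planes <- planes[keep]
        seed_idx <- seed_idx[keep]
        m <- nrow(X)
      }
    }
    structure(list(positions = X, lambda = lambda,
                   radius = rep(r, m), planes = planes,
                   support = support,
                   seed_idx = seed_idx, spacing = spacing,
                   movement_trace = movement_trace, params = params),
              class = "skeleton_points")
  })
}

#' @export
print.skeleton_points <- function(x, ...) {
  cat(sprintf("skeleton_points: %d points, final radius %.2f mm, %d outer iterations\n",
              nrow(x$positions), x$radius[1], length(x$movement_trace)))
  invisible(x)
}

#' Export skeleton points to CSV
#' @param skel a `skeleton_points`.
#' @param path output CSV path (columns x, y, z, lambda, radius).
#' @return `path` invisibly.
#' @export
write_skeleton_csv <- function(skel, path) {
  df <- data.frame(x = skel$positions[, 1], y = skel$positions[, 2],
                   z = skel$positions[, 3], lambda = skel$lambda,
                   radius = skel$radius)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
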