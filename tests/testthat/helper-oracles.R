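# Independent oracles and fixture builders. Everything here is deliberately
# naive (exhaustive search, textbook formulas) so it cannot share a bug with
# the implementation under test.

# geometric median by plain Weiszfeld iteration followed by local grid
# refinement of the objective sum(|x - p_j|)
oracle_geometric_median <- function(points, tol = 1e-10) {
  obj <- function(x) sum(sqrt(rowSums(sweep(points, 2, x)^2)))
  x <- colMeans(points)
  for (i in 1:2000) {
    d <- pmax(sqrt(rowSums(sweep(points, 2, x)^2)), 1e-12)
    x_new <- colSums(points / d) / sum(1 / d)
    if (sqrt(sum((x_new - x)^2)) < tol) break
    x <- x_new
  }
  # grid refinement in shrinking boxes around the Weiszfeld solution
  h <- 1e-3
  for (level in 1:6) {
    g <- as.matrix(expand.grid(x[1] + h * (-2:2), x[2] + h * (-2:2),
                               x[3] + h * (-2:2)))
    vals <- apply(g, 1, obj)
    x <- g[which.min(vals), ]
    h <- h / 3
  }
  unname(x)
}

# exhaustive textbook DBSCAN: reachability closure over the full distance
# matrix
oracle_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    repeat {
      members <- which(labels == cl)
      reach <- sort(unique(unlist(nb[members[core[members]]])))
      reach <- reach[labels[reach] == 0L]
      if (length(reach) == 0) break
      labels[reach] <- cl
    }
  }
  labels
}

# exact shortest Hamiltonian path over <= 12 points (Held-Karp dynamic
# program over vertex subsets, with path reconstruction)
oracle_shortest_path <- function(pts) {
  n <- nrow(pts)
  stopifnot(n <= 12)
  D <- as.matrix(dist(pts))
  full <- bitwShiftL(1L, n) - 1L
  dp <- matrix(Inf, full, n)       # dp[mask, j]: best path over mask ending j
  par <- matrix(0L, full, n)
  for (j in seq_len(n)) dp[bitwShiftL(1L, j - 1L), j] <- 0
  for (mask in seq_len(full)) {
    for (j in seq_len(n)) {
      if (!bitwAnd(mask, bitwShiftL(1L, j - 1L)) || is.infinite(dp[mask, j]))
        next
      for (k in seq_len(n)) {
        bit <- bitwShiftL(1L, k - 1L)
        if (bitwAnd(mask, bit)) next
        nm <- bitwOr(mask, bit)
        cand <- dp[mask, j] + D[j, k]
        if (cand < dp[nm, k]) { dp[nm, k] <- cand; par[nm, k] <- j }
      }
    }
  }
  endj <- which.min(dp[full, ])
  best <- dp[full, endj]
  ord <- integer(n)
  mask <- full; j <- endj
  for (t in n:1) {
    ord[t] <- j
    pj <- par[mask, j]
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
    j <- pj
  }
  list(length = best, order = ord)
}

# circle fit oracle: 2-parameter grid refinement of squared residuals for
# the center, radius as mean distance (optimal given a center)
oracle_circle <- function(pts2d) {
  obj <- function(c2) {
    d <- sqrt((pts2d[, 1] - c2[1])^2 + (pts2d[, 2] - c2[2])^2)
    sum((d - mean(d))^2)
  }
  ctr <- colMeans(pts2d)
  h <- 1
  for (level in 1:12) {
    g <- as.matrix(expand.grid(ctr[1] + h * (-3:3), ctr[2] + h * (-3:3)))
    vals <- apply(g, 1, obj)
    ctr <- g[which.min(vals), ]
    h <- h / 2.5
  }
  d <- sqrt((pts2d[, 1] - ctr[1])^2 + (pts2d[, 2] - ctr[2])^2)
  list(center = unname(ctr), radius = mean(d))
}

# exhaustive-sample RANSAC plane oracle on a small subsample: tries every
# 3-point combination and picks the plane with most inliers, then refits
oracle_plane <- function(pts, inlier_tol) {
  n <- nrow(pts)
  best_count <- -1L
  best <- NULL
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    v1 <- pts[j, ] - pts[i, ]; v2 <- pts[k, ] - pts[i, ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    if (sqrt(sum(nrm^2)) < 1e-12) next
    nrm <- nrm / sqrt(sum(nrm^2))
    d <- abs(sweep(pts, 2, pts[i, ]) %*% nrm)
    cnt <- sum(d < inlier_tol)
    if (cnt > best_count) { best_count <- cnt; best <- nrm }
  }
  best
}

## ---- fixture builders ---------------------------------------------------

# surface point sample of a straight cylindrical tube along `axis_dir`
make_tube <- function(n, radius, length, base = c(0, 0, 0),
                      axis_dir = c(0, 0, 1), noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
    ref <- if (abs(axis_dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * axis_dir) * axis_dir
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis_dir[2] * e1[3] - axis_dir[3] * e1[2],
            axis_dir[3] * e1[1] - axis_dir[1] * e1[3],
            axis_dir[1] * e1[2] - axis_dir[2] * e1[1])
    t <- runif(n, 0, length)
    a <- runif(n, 0, 2 * pi)
    pts <- matrix(base, n, 3, byrow = TRUE) + outer(t, axis_dir) +
      radius * (outer(cos(a), e1) + outer(sin(a), e2))
    if (noise_sd > 0) pts <- pts + matrix(rnorm(3 * n, 0, noise_sd), n, 3)
    pts
  })
}

# surface sample of a flat box pod (width w, thickness th) along +x
make_flat_pod <- function(len = 60, w = 3, th = 1.5, density = 1,
                          base = c(0, 0, 0), dir = c(1, 0, 0),
                          e_w = c(0, 1, 0), noise_sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    dir <- dir / sqrt(sum(dir^2))
    e_w <- e_w - sum(e_w * dir) * dir
    e_w <- e_w / sqrt(sum(e_w^2))
    e_t <- c(dir[2] * e_w[3] - dir[3] * e_w[2],
             dir[3] * e_w[1] - dir[1] * e_w[3],
             dir[1] * e_w[2] - dir[2] * e_w[1])
    areas <- c(len * w, len * w, len * th, len * th)
    ns <- rpois(4, areas * density)
    u <- runif(sum(ns), 0, len)
    ww <- c(runif(ns[1], -w / 2, w / 2), runif(ns[2], -w / 2, w / 2),
            rep(w / 2, ns[3]), rep(-w / 2, ns[4]))
    tt <- c(rep(th / 2, ns[1]), rep(-th / 2, ns[2]),
            runif(ns[3], -th / 2, th / 2), runif(ns[4], -th / 2, th / 2))
    pts <- matrix(base, sum(ns), 3, byrow = TRUE) + outer(u, dir) +
      outer(ww, e_w) + outer(tt, e_t)
    if (noise_sd > 0)
      pts <- pts + matrix(rnorm(length(pts), 0, noise_sd), nrow(pts), 3)
    pts
  })
}

# uniform volume sample of an axis-aligned box (solid), along +x
make_box_points <- function(n, lx, ly, lz, seed = 1) {
  withr::with_seed(seed,
    cbind(runif(n, 0, lx), runif(n, -ly / 2, ly / 2),
          runif(n, -lz / 2, lz / 2)))
}

# ordered samples along a smooth 3D curve, with the generative order
make_curve_class <- function(n, kind = c("line", "L", "arc"), seed = 1,
                             spacing = 1) {
  kind <- match.arg(kind)
  withr::with_seed(seed, {
    t <- seq(0, 1, length.out = n)
    pts <- switch(kind,
      line = cbind(t * (n - 1) * spacing, 0, 0),
      L = {
        half <- floor(n / 2)
        rbind(cbind(seq_len(half) * spacing, 0, 0),
              cbind(half * spacing, seq_len(n - half) * spacing, 0))
      },
      arc = {
        ang <- t * pi / 2
        R <- (n - 1) * spacing * 2 / pi
        cbind(R * cos(ang), R * sin(ang), 0)
      })
    pts + matrix(rnorm(3 * nrow(pts), 0, 0.02 * spacing), nrow(pts), 3)
  })
}

# random 3D rotation matrix
random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
    matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
             2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
             2 * (b * d - a * c), 2 * (c * d + a * b),
             a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
  })
}
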