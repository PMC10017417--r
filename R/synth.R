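#' Synthetic plant specification
#'
#' Describes a labeled synthetic oilseed-rape plant at the mature (silique)
#' stage: one of three branch architectures — few-branch broom (FBBS),
#' multibranch broom (MBBS), multibranch cylinder (MBCS) — with flat,
#' elongate siliques attached to the branches by short thin pedicels, an
#' optional inverted-frustum pot, per-organ sector occlusion emulating the
#' partial horizontal coverage of a handheld scan, and Gaussian sensor noise.
#' Branch-count defaults follow the average counts observed per architecture
#' (first/second/third branches: FBBS 1/3.7/0.1, MBBS 1.3/6.3/4.3,
#' MBCS 4.2/14.2/6.2).
#'
#' @param architecture `"FBBS"`, `"MBBS"` or `"MBCS"`.
#' @param n_first,n_second,n_third branch counts; NULL draws them around the
#'   architecture's average (at least one first branch).
#' @param n_siliques number of siliques to place (default 40).
#' @param silique_len_mean,silique_len_sd silique length distribution in mm
#'   (default N(60, 8^2), truncated at 25 mm).
#' @param silique_width,silique_thickness flat rectangular cross-section in
#'   mm (default 3 x 1.5).
#' @param stem_radius,branch_radius tube radii in mm (defaults 2 and 1.4).
#' @param density surface sampling density in points/mm^2 (default 1).
#' @param noise_sd Gaussian coordinate noise in mm (default 0.05, the
#'   scanner's spatial resolution).
#' @param occlusion_fraction per-organ contiguous angular dropout in `[0, 1)`
#'   (default 1/3, emulating 240 of 360 degrees of horizontal coverage).
#' @param pot frustum as `list(r_bottom, r_top, height)` in mm, or NULL for
#'   no pot (default 40/60/100).
#' @param seed integer seed; generation is deterministic per seed.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(architecture = c("FBBS", "MBBS", "MBCS"),
                       n_first = NULL, n_second = NULL, n_third = NULL,
                       n_siliques = 40,
                       silique_len_mean = 60, silique_len_sd = 8,
                       silique_width = 3, silique_thickness = 1.5,
                       stem_radius = 2, branch_radius = 1.4,
                       density = 1.0, noise_sd = 0.05,
                       occlusion_fraction = 1 / 3,
                       pot = list(r_bottom = 40, r_top = 60, height = 100),
                       seed = 1) {
  architecture <- match.arg(architecture)
  stopifnot(n_siliques >= 0, density > 0, noise_sd >= 0,
            occlusion_fraction >= 0, occlusion_fraction < 1)
  structure(list(architecture = architecture, n_first = n_first,
                 n_second = n_second, n_third = n_third,
                 n_siliques = n_siliques,
                 silique_len_mean = silique_len_mean,
                 silique_len_sd = silique_len_sd,
                 silique_width = silique_width,
                 silique_thickness = silique_thickness,
                 stem_radius = stem_radius, branch_radius = branch_radius,
                 density = density, noise_sd = noise_sd,
                 occlusion_fraction = occlusion_fraction, pot = pot,
                 seed = seed),
            class = "plant_spec")
}

.BRANCH_MEANS <- list(FBBS = c(1, 3.69, 0.08),
                      MBBS = c(1.33, 6.33, 4.33),
                      MBCS = c(4.20, 14.20, 6.20))

.unit <- function(v) v / sqrt(sum(v^2))

# two unit vectors orthogonal to v
.orthobasis <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(ref - sum(ref * v) * v)
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# rotate `dir` by `angle` (rad) away from itself, toward azimuth `az` in its
# orthogonal plane
.tilt <- function(dir, angle, az) {
  b <- .orthobasis(dir)
  .unit(cos(angle) * dir +
          sin(angle) * (cos(az) * b$e1 + sin(az) * b$e2))
}

# sample a cylindrical tube surface; returns points and each point's
# azimuth around the tube axis (for sector occlusion)
.sample_tube <- function(base, dir, len, radius, density) {
  n <- rpois(1, 2 * pi * radius * len * density)
  if (n == 0) return(list(pts = matrix(0, 0, 3), az = numeric(0)))
  b <- .orthobasis(dir)
  t <- runif(n, 0, len)
  az <- runif(n, 0, 2 * pi)
  pts <- matrix(base, n, 3, byrow = TRUE) + outer(t, dir) +
    radius * (outer(cos(az), b$e1) + outer(sin(az), b$e2))
  list(pts = pts, az = az)
}

# sample the surface of a flat box (rectangular cross-section w x th) of
# length len along dir, width along e_w; returns points + azimuths
.sample_flat_pod <- function(base, dir, e_w, len, w, th, density) {
  e_t <- c(dir[2] * e_w[3] - dir[3] * e_w[2],
           dir[3] * e_w[1] - dir[1] * e_w[3],
           dir[1] * e_w[2] - dir[2] * e_w[1])
  # faces: 2 of len x w (normal e_t), 2 of len x th (normal e_w), 2 caps
  areas <- c(len * w, len * w, len * th, len * th, w * th, w * th)
  counts <- rpois(6, areas * density)
  n <- sum(counts)
  if (n == 0) return(list(pts = matrix(0, 0, 3), az = numeric(0)))
  uu <- numeric(0); ww <- numeric(0); tt <- numeric(0)
  for (f in seq_len(6)) {
    k <- counts[f]
    if (k == 0) next
    if (f <= 2) {          # wide faces at +-th/2
      uu <- c(uu, runif(k, 0, len))
      ww <- c(ww, runif(k, -w / 2, w / 2))
      tt <- c(tt, rep(ifelse(f == 1, th / 2, -th / 2), k))
    } else if (f <= 4) {   # narrow faces at +-w/2
      uu <- c(uu, runif(k, 0, len))
      ww <- c(ww, rep(ifelse(f == 3, w / 2, -w / 2), k))
      tt <- c(tt, runif(k, -th / 2, th / 2))
    } else {               # end caps
      uu <- c(uu, rep(ifelse(f == 5, 0, len), k))
      ww <- c(ww, runif(k, -w / 2, w / 2))
      tt <- c(tt, runif(k, -th / 2, th / 2))
    }
  }
  pts <- matrix(base, n, 3, byrow = TRUE) + outer(uu, dir) +
    outer(ww, e_w) + outer(tt, e_t)
  list(pts = pts, az = atan2(tt, ww) %% (2 * pi))
}

# frustum lateral surface (pot): radius r_bottom at z0 growing to r_top
.sample_frustum <- function(center_xy, z0, r_bottom, r_top, height, density) {
  slant <- sqrt(height^2 + (r_top - r_bottom)^2)
  area <- pi * (r_bottom + r_top) * slant
  n <- rpois(1, area * density)
  if (n == 0) return(list(pts = matrix(0, 0, 3), az = numeric(0)))
  # area element grows with radius: sample height by inverse cdf
  u <- runif(n)
  if (abs(r_top - r_bottom) < 1e-9) {
    hfrac <- u
  } else {
    a <- r_bottom; bb <- r_top - r_bottom
    hfrac <- (sqrt(a^2 + u * (2 * a * bb + bb^2)) - a) / bb
  }
  r <- r_bottom + (r_top - r_bottom) * hfrac
  az <- runif(n, 0, 2 * pi)
  pts <- cbind(center_xy[1] + r * cos(az), center_xy[2] + r * sin(az),
               z0 + hfrac * height)
  list(pts = pts, az = az)
}

# drop a contiguous angular sector (one per organ)
.occlude <- function(samp, frac) {
  if (frac <= 0 || length(samp$az) == 0) return(samp$pts)
  start <- runif(1, 0, 2 * pi)
  rel <- (samp$az - start) %% (2 * pi)
  samp$pts[rel >= frac * 2 * pi, , drop = FALSE]
}

#' Generate a labeled synthetic plant
#'
#' Builds the plant described by a [plant_spec()]: near-vertical first
#' branches (main stems) rising from the pot top, straight second/third
#' branches at realistic insertion angles, siliques as flat boxes attached by
#' thin sparse pedicels at 20-70 degree pedicel angles, spread along the
#' branches with golden-angle azimuths. Surfaces are Poisson-sampled at
#' `density`, each organ loses one contiguous angular sector
#' (`occlusion_fraction` of its circumference), and Gaussian noise of sd
#' `noise_sd` is added. Every point carries a label (0 = pot, branch ids,
#' silique ids); the ground truth records each silique's axis, true length,
#' and analytic volume (cross-section area x length). A silique placement
#' that cannot find clearance from already-placed siliques is retried at new
#' attachment slots (with a warning if clearance is never found).
#'
#' @param spec a [plant_spec()].
#' @return list with `cloud` (a labeled [point_cloud()]) and `truth`
#'   (labels legend, silique table with axes, branch table, totals).
#' @export
generate_plant <- function(spec = plant_spec()) {
  stopifnot(inherits(spec, "plant_spec"))
  with_local_seed(spec$seed, .generate_plant_impl(spec))
}

.generate_plant_impl <- function(spec) {
  mu <- .BRANCH_MEANS[[spec$architecture]]
  n1 <- spec$n_first %||% max(1L, rpois(1, mu[1]))
  n2 <- spec$n_second %||% rpois(1, mu[2])
  n3 <- spec$n_third %||% rpois(1, mu[3])
  z0 <- if (is.null(spec$pot)) 0 else spec$pot$height
  spread <- if (spec$architecture == "MBCS") 12 else 6   # deg tilt of stems

  branches <- list()   # each: base, dir, len, radius, parent level
  for (i in seq_len(n1)) {
    az <- 2 * pi * (i - 1) / max(1, n1) + runif(1, 0, 0.5)
    dir <- .tilt(c(0, 0, 1), (spread * pi / 180) * runif(1, 0.3, 1), az)
    branches[[length(branches) + 1]] <-
      list(base = c(0, 0, z0), dir = dir, len = runif(1, 420, 560),
           radius = spec$stem_radius, level = 1L)
  }
  first_ids <- seq_along(branches)
  golden <- pi * (3 - sqrt(5))
  for (i in seq_len(n2)) {
    par <- branches[[first_ids[1 + (i - 1) %% length(first_ids)]]]
    at <- par$base + runif(1, 0.25, 0.75) * par$len * par$dir
    dir <- .tilt(par$dir, runif(1, 30, 60) * pi / 180, golden * i + runif(1, 0, 0.4))
    branches[[length(branches) + 1]] <-
      list(base = at, dir = dir, len = runif(1, 230, 350),
           radius = spec$branch_radius, level = 2L)
  }
  second_ids <- which(vapply(branches, `[[`, 0L, "level") == 2L)
  for (i in seq_len(n3)) {
    pid <- if (length(second_ids)) second_ids[1 + (i - 1) %% length(second_ids)]
           else first_ids[1 + (i - 1) %% length(first_ids)]
    par <- branches[[pid]]
    at <- par$base + runif(1, 0.3, 0.8) * par$len * par$dir
    dir <- .tilt(par$dir, runif(1, 30, 60) * pi / 180, golden * i + 1 + runif(1, 0, 0.4))
    branches[[length(branches) + 1]] <-
      list(base = at, dir = dir, len = runif(1, 210, 260),
           radius = spec$branch_radius, level = 3L)
  }
  nb <- length(branches)

  # attachment slots: siliques pack densely on the terminal raceme of each
  # branch (about every 10 mm), and racemes fill one branch after another —
  # lower branch spans stay bare, as on real mature plants. Second and
  # third branches bear pods before the main stems' own racemes.
  slots <- list()
  border <- order(vapply(branches, `[[`, 0L, "level") == 1L)  # stems last
  for (bi in border) {
    b <- branches[[bi]]
    lo <- if (b$level == 1L) 0.6 * b$len else 0.45 * b$len
    hi <- 0.95 * b$len
    if (hi <= lo) next
    for (s in seq(lo, hi, by = 10)) {
      slots[[length(slots) + 1]] <- list(branch = bi, t = s)
    }
  }
  if (spec$n_siliques > 0 && length(slots) == 0)
    stop("plant has no branch span to attach siliques to")
  slot_order <- seq_along(slots)

  # silique placement with clearance retries
  sil <- list()
  axis_samples <- matrix(numeric(0), 0, 3)
  clearance <- spec$silique_width + 3
  si <- 0L
  used <- 0L
  warned <- FALSE
  while (si < spec$n_siliques) {
    si <- si + 1L
    len <- max(25, rnorm(1, spec$silique_len_mean, spec$silique_len_sd))
    placed <- FALSE
    for (try in seq_len(30)) {
      used <- used + 1L
      slot <- slots[[slot_order[1 + (used - 1) %% length(slot_order)]]]
      b <- branches[[slot$branch]]
      at <- b$base + slot$t * b$dir
      dir <- .tilt(b$dir, runif(1, 20, 70) * pi / 180,
                   golden * used + runif(1, 0, 0.6))
      ped_len <- runif(1, 10, 18)
      base <- at + b$radius * .unit(dir - sum(dir * b$dir) * b$dir) +
        ped_len * dir
      ax <- base + outer(seq(0, len, by = 5), dir)
      if (nrow(axis_samples) > 0) {
        mind <- min(cpp_knn_dist(axis_samples, ax, 1L, FALSE))
        if (mind < clearance) next
      }
      roll <- runif(1, 0, pi)
      bb <- .orthobasis(dir)
      e_w <- .unit(cos(roll) * bb$e1 + sin(roll) * bb$e2)
      sil[[si]] <- list(attach = at, base = base, dir = dir, e_w = e_w,
                        len = len, ped_len = ped_len, branch = slot$branch)
      axis_samples <- rbind(axis_samples, ax)
      placed <- TRUE
      break
    }
    if (!placed) {
      if (!warned) {
        warning("could not find clearance for every silique; ",
                "placing the remainder without a clearance guarantee")
        warned <- TRUE
      }
      slot <- slots[[slot_order[1 + (used - 1) %% length(slot_order)]]]
      b <- branches[[slot$branch]]
      at <- b$base + slot$t * b$dir
      dir <- .tilt(b$dir, runif(1, 20, 70) * pi / 180, golden * used)
      ped_len <- runif(1, 10, 18)
      base <- at + b$radius * .unit(dir - sum(dir * b$dir) * b$dir) +
        ped_len * dir
      roll <- runif(1, 0, pi)
      bb <- .orthobasis(dir)
      e_w <- .unit(cos(roll) * bb$e1 + sin(roll) * bb$e2)
      sil[[si]] <- list(attach = at, base = base, dir = dir, e_w = e_w,
                        len = len, ped_len = ped_len, branch = slot$branch)
      axis_samples <- rbind(axis_samples, base + outer(seq(0, len, by = 5), dir))
    }
  }

  # ---- sample all surfaces ----
  pts <- list(); labs <- list()
  if (!is.null(spec$pot)) {
    samp <- .sample_frustum(c(0, 0), 0, spec$pot$r_bottom, spec$pot$r_top,
                            spec$pot$height, spec$density)
    p <- .occlude(samp, spec$occlusion_fraction)
    pts[[length(pts) + 1]] <- p
    labs[[length(labs) + 1]] <- rep(0L, nrow(p))
  }
  for (bi in seq_len(nb)) {
    b <- branches[[bi]]
    samp <- .sample_tube(b$base, b$dir, b$len, b$radius, spec$density)
    p <- .occlude(samp, spec$occlusion_fraction)
    pts[[length(pts) + 1]] <- p
    labs[[length(labs) + 1]] <- rep(bi, nrow(p))
  }
  for (k in seq_along(sil)) {
    s <- sil[[k]]
    # sparse thin pedicel, labeled with its parent branch
    ped <- .sample_tube(s$attach, s$dir, s$ped_len, 0.25, spec$density)
    p <- .occlude(ped, spec$occlusion_fraction)
    pts[[length(pts) + 1]] <- p
    labs[[length(labs) + 1]] <- rep(s$branch, nrow(p))
    pod <- .sample_flat_pod(s$base, s$dir, s$e_w, s$len, spec$silique_width,
                            spec$silique_thickness, spec$density)
    p <- .occlude(pod, spec$occlusion_fraction)
    pts[[length(pts) + 1]] <- p
    labs[[length(labs) + 1]] <- rep(nb + k, nrow(p))
  }
  points <- do.call(rbind, pts)
  labels <- unlist(labs)
  if (spec$noise_sd > 0)
    points <- points + matrix(rnorm(length(points), 0, spec$noise_sd),
                              nrow(points), 3)

  sil_tab <- if (length(sil)) data.frame(
    id = seq_along(sil),
    label = nb + seq_along(sil),
    branch = vapply(sil, `[[`, 0L, "branch"),
    true_length = vapply(sil, `[[`, 0, "len"),
    true_volume = vapply(sil, `[[`, 0, "len") * spec$silique_width *
      spec$silique_thickness
  ) else data.frame(id = integer(0), label = integer(0), branch = integer(0),
                    true_length = numeric(0), true_volume = numeric(0))
  branch_tab <- data.frame(
    id = seq_len(nb),
    level = vapply(branches, `[[`, 0L, "level"),
    length = vapply(branches, `[[`, 0, "len")
  )
  truth <- list(
    siliques = sil_tab,
    silique_axes = lapply(sil, function(s)
      rbind(s$base, s$base + s$len * s$dir)),
    branches = branch_tab,
    branch_axes = lapply(branches, function(b)
      rbind(b$base, b$base + b$len * b$dir)),
    sn = nrow(sil_tab),
    total_sl = sum(sil_tab$true_length),
    total_sv = sum(sil_tab$true_volume),
    pot_label = if (is.null(spec$pot)) NA_integer_ else 0L,
    spec = spec
  )
  list(cloud = point_cloud(points, labels = labels), truth = truth)
}

#' Degrade a synthetic cloud
#'
#' Adds extra Gaussian noise and/or random point dropout for robustness
#' sweeps. Labels follow the surviving points; the ground truth is not
#' touched. With zero noise and zero dropout the cloud is returned unchanged.
#'
#' @param cloud a [point_cloud()].
#' @param extra_noise_sd additional Gaussian noise sd in mm.
#' @param dropout_fraction fraction of points removed uniformly at random,
#'   in `[0, 1)`.
#' @param seed integer seed.
#' @return the degraded `point_cloud`.
#' @export
degrade <- function(cloud, extra_noise_sd = 0, dropout_fraction = 0,
                    seed = 1) {
  stopifnot(dropout_fraction >= 0, dropout_fraction < 1, extra_noise_sd >= 0)
  if (extra_noise_sd == 0 && dropout_fraction == 0) return(cloud)
  with_local_seed(seed, {
    out <- cloud
    if (dropout_fraction > 0) {
      keep <- runif(n_points(out)) >= dropout_fraction
      out <- pc_subset(out, which(keep))
    }
    if (extra_noise_sd > 0) {
      out$points <- out$points +
        matrix(rnorm(length(out$points), 0, extra_noise_sd),
               nrow(out$points), 3)
    }
    out
  })
}

#' Write a synthetic plant to disk
#'
#' Writes the labeled cloud (PLY with a `label` vertex property), the
#' ground-truth summary (JSON) and the per-silique table (CSV).
#'
#' @param plant a list from [generate_plant()].
#' @param dir output directory (created if needed).
#' @param name file stem (default "plant").
#' @return the directory, invisibly.
#' @export
write_plant <- function(plant, dir, name = "plant") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cloud(plant$cloud, file.path(dir, paste0(name, ".ply")))
  write.csv(plant$truth$siliques,
            file.path(dir, paste0(name, "_siliques.csv")), row.names = FALSE)
  truth <- plant$truth
  truth$silique_axes <- NULL
  truth$branch_axes <- NULL
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, paste0(name, "_truth.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
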