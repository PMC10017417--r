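#' Algebraic least-squares circle fit
#'
#' Fits a circle to 2D points by the algebraic (Kasa) least-squares method:
#' solving `2ax + 2by + c = x^2 + y^2` for the center (a, b) and
#' `r = sqrt(c + a^2 + b^2)`.
#'
#' @param points2d numeric matrix with 2 columns (x, y); at least 3
#'   non-collinear points.
#' @return list with `center` (length-2) and `radius`.
#' @export
fit_circle_lsm <- function(points2d) {
  points2d <- as.matrix(points2d)
  if (nrow(points2d) < 3)
    stop("circle fit needs at least 3 points, got ", nrow(points2d))
  x <- points2d[, 1]; y <- points2d[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  qrA <- qr(A)
  if (qrA$rank < 3)
    stop("degenerate geometry: points are collinear, no unique circle")
  sol <- qr.coef(qrA, x^2 + y^2)
  center <- sol[1:2]
  r2 <- sol[3] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0)
    stop("degenerate geometry: circle fit failed")
  list(center = unname(center), radius = sqrt(r2))
}

#' Detect the pot by stacked circle fits
#'
#' Plant pots approximate an inverted frustum of a cone: slab-wise circle
#' radii grow from the bottom up. Starting at the lowest point, each z-slab of
#' thickness `delta_d` is projected to the ground plane and fitted with a
#' least-squares circle; fitting continues upward while the radius keeps
#' growing (by more than `grow_tol` relative, to absorb fit noise). The last
#' growing slab defines the maximum circle `r_max`/`o_max`, and the pot height
#' `h` spans from the lowest point to the top edge of that slab. If the radius
#' never grows past the first slab the cloud is treated as having no pot
#' (`h = 0`).
#'
#' @param cloud a nonempty [point_cloud()].
#' @param delta_d slab thickness in mm (default 10).
#' @param grow_tol minimum relative radius increase per slab to count as
#'   still growing (default 0.02).
#' @return an object of class `pot_model`: slab circle table, `r_max`,
#'   `o_max`, `h`, `z_min`, `delta_d`.
#' @export
detect_pot <- function(cloud, delta_d = 10, grow_tol = 0.02) {
  if (n_points(cloud) == 0) stop("cannot detect a pot in an empty cloud")
  stopifnot(delta_d > 0)
  z <- cloud$points[, 3]
  z_min <- min(z)
  z_max <- max(z)
  n_slabs <- max(1L, ceiling((z_max - z_min) / delta_d))
  slabs <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                      z_low = numeric(0))
  for (ns in seq_len(n_slabs)) {
    lo <- z_min + (ns - 1) * delta_d
    hi <- z_min + ns * delta_d
    idx <- which(z >= lo & (z < hi | (ns == n_slabs & z <= hi)))
    if (length(idx) < 3) {
      if (ns == 1) stop("bottom slab has fewer than 3 points; cannot fit pot")
      break
    }
    fit <- tryCatch(fit_circle_lsm(cloud$points[idx, 1:2, drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) {
      if (ns == 1) stop("bottom slab circle fit is degenerate")
      break
    }
    if (ns > 1 && fit$radius <= slabs$r[ns - 1] * (1 + grow_tol)) break
    slabs[ns, ] <- c(fit$center, fit$radius, lo)
  }
  i_max <- nrow(slabs)          # radii strictly increase along accepted slabs
  h <- if (i_max <= 1) 0 else (slabs$z_low[i_max] + delta_d) - z_min
  structure(list(slabs = slabs,
                 r_max = slabs$r[i_max],
                 o_max = c(slabs$cx[i_max], slabs$cy[i_max]),
                 h = h, z_min = z_min, delta_d = delta_d),
            class = "pot_model")
}

#' @export
print.pot_model <- function(x, ...) {
  cat(sprintf("pot_model: %d slab circle(s), r_max = %.2f mm, h = %.2f mm\n",
              nrow(x$slabs), x$r_max, x$h))
  invisible(x)
}

#' Remove pot points
#'
#' Removes every point with z in `[z_min, z_min + h]` whose ground-plane
#' projection falls inside its slab's fitted circle (or inside the `r_max`
#' circle when the slab has no fit of its own, or when `use_slab_circles` is
#' `FALSE`). A small radial margin keeps pot-wall surface points, which
#' scatter around the fitted circle, inside the cull. Points above the pot
#' height are never removed; a plant stem passing through the pot interior
#' below `z_min + h` is removed with it (documented collateral).
#'
#' @param cloud the same [point_cloud()] the pot was detected on.
#' @param pot a `pot_model` from [detect_pot()].
#' @param use_slab_circles test each slab against its own circle (default)
#'   rather than the global `r_max` circle.
#' @param margin radial margin in mm added to each circle (default 2: the
#'   circle is fitted mid-slab while the frustum wall keeps sloping outward
#'   within the slab).
#' @return the `point_cloud` without pot points.
#' @export
remove_pot <- function(cloud, pot, use_slab_circles = TRUE, margin = 2.0) {
  if (n_points(cloud) == 0) return(cloud)
  p <- cloud$points
  z <- p[, 3]
  in_band <- z >= pot$z_min & z <= pot$z_min + pot$h
  drop <- rep(FALSE, nrow(p))
  if (any(in_band)) {
    idx <- which(in_band)
    slab_no <- pmin(pmax(floor((z[idx] - pot$z_min) / pot$delta_d) + 1, 1),
                    max(1, ceiling(pot$h / pot$delta_d)))
    if (use_slab_circles) {
      cx <- pot$slabs$cx[slab_no]; cy <- pot$slabs$cy[slab_no]
      r <- pot$slabs$r[slab_no]
      miss <- is.na(r)
      if (any(miss)) {
        cx[miss] <- pot$o_max[1]; cy[miss] <- pot$o_max[2]
        r[miss] <- pot$r_max
      }
    } else {
      cx <- pot$o_max[1]; cy <- pot$o_max[2]; r <- pot$r_max
    }
    d2 <- (p[idx, 1] - cx)^2 + (p[idx, 2] - cy)^2
    drop[idx] <- d2 <= (r + margin)^2
  }
  pc_subset(cloud, which(!drop))
}
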