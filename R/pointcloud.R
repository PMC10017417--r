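#' Point cloud container
#'
#' A minimal container for an unordered 3D point cloud in millimetres, with an
#' optional per-point integer label (organ/class id; `-1` means unassigned)
#' and an optional data frame of extra per-vertex attributes (e.g. colors or
#' normals read from a PLY file) that are preserved on write.
#'
#' @param points numeric matrix with columns x, y, z (mm).
#' @param labels optional integer vector, one label per point.
#' @param attrs optional data.frame of extra per-vertex attributes.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(points, labels = NULL, attrs = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  .assert_points3(points)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(points))
      stop("label count (", length(labels), ") does not equal point count (",
           nrow(points), ")")
  }
  if (!is.null(attrs)) {
    attrs <- as.data.frame(attrs)
    if (nrow(attrs) != nrow(points))
      stop("attrs row count does not equal point count")
  }
  structure(list(points = points, labels = labels, attrs = attrs),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' @export
print.point_cloud <- function(x, ...) {
  cat("point_cloud:", nrow(x$points), "points")
  if (!is.null(x$labels))
    cat(",", length(unique(x$labels[x$labels >= 0])), "labeled classes")
  if (nrow(x$points) > 0) {
    rng <- apply(x$points, 2, range)
    cat(sprintf("\n  extent (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  cat("\n")
  invisible(x)
}

# subset a cloud by point index, keeping labels/attrs aligned
pc_subset <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              labels = if (!is.null(cloud$labels)) cloud$labels[idx],
              attrs  = if (!is.null(cloud$attrs))
                cloud$attrs[idx, , drop = FALSE])
}

#' Voxel-grid downsampling
#'
#' Keeps one representative point (the first by input order, deterministic)
#' per occupied cubic voxel. Labels and attributes follow the kept points.
#'
#' @param cloud a `point_cloud`.
#' @param voxel voxel edge length in mm.
#' @return a downsampled `point_cloud`.
#' @export
voxel_downsample <- function(cloud, voxel) {
  stopifnot(voxel > 0)
  if (n_points(cloud) == 0) return(cloud)
  p <- cloud$points
  ijk <- floor(sweep(p, 2, apply(p, 2, min)) / voxel)
  key <- ijk[, 1] + 1e6 * (ijk[, 2] + 1e6 * ijk[, 3])
  keep <- !duplicated(key)
  pc_subset(cloud, which(keep))
}
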