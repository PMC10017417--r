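#' Statistical outlier removal
#'
#' Classic statistical filter for scanner noise: computes each point's mean
#' distance to its `k` nearest neighbors and removes points whose mean exceeds
#' the global mean plus `std_ratio` standard deviations of that statistic.
#'
#' @param cloud a [point_cloud()] with more than `k` points.
#' @param k number of nearest neighbors (default 20).
#' @param std_ratio threshold in standard deviations (default 2).
#' @return the filtered `point_cloud`.
#' @export
remove_outliers <- function(cloud, k = 20, std_ratio = 2.0) {
  n <- n_points(cloud)
  if (n <= k)
    stop("cloud has ", n, " points; need more than k = ", k,
         " for the statistical filter")
  d <- cpp_knn_dist(cloud$points, cloud$points, as.integer(k), TRUE)
  mu_i <- rowMeans(d)
  thr <- mean(mu_i) + std_ratio * sd(mu_i)
  pc_subset(cloud, which(mu_i <= thr))
}

# k-nearest-neighbor distances within one point set (self excluded);
# returns an n x k matrix of distances
knn_distances <- function(points, k = 1) {
  .assert_points3(points)
  cpp_knn_dist(points, points, as.integer(k), TRUE)
}

# mean / median nearest-neighbor spacing of a point set
nn_spacing <- function(points, stat = mean) {
  if (nrow(points) < 2) return(NA_real_)
  stat(knn_distances(points, 1)[, 1])
}

# radius search: indices of `data` rows within r of each `query` row
radius_neighbors <- function(data, query, r) {
  cpp_radius_neighbors(data, query, r)
}
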