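#' Statistical outlier removal by k-nearest-neighbor distances
#'
#' Computes every point's mean distance to its `k_neighbors` nearest
#' neighbors and removes the points whose mean distance exceeds
#' `mean + alpha * sd` of those distances over the whole cloud. Isolated
#' points left around the recognized crop by the clustering step are far
#' from their neighbors and get cut; survivors keep their input order.
#'
#' @param cloud A finite [point_cloud()].
#' @param k_neighbors Number of neighbors (default 10).
#' @param alpha Standard-deviation multiplier for the cut (default 1).
#' @return The filtered `point_cloud`, with attribute `"removed"` giving
#'   the indices of the removed points.
#' @export
knn_outlier_filter <- function(cloud, k_neighbors = 10, alpha = 1) {
  stopifnot(inherits(cloud, "point_cloud"), k_neighbors >= 1, alpha > 0)
  n <- cloud$count
  if (n <= k_neighbors) {
    warning(sprintf("cloud has %d <= k = %d points: returned unchanged",
                    n, k_neighbors))
    return(cloud)
  }
  dbar <- cpp_knn_mean_dist(cloud$points, as.integer(k_neighbors))
  cut <- mean(dbar) + alpha * sd(dbar)
  keep <- dbar <= cut
  out <- point_cloud(cloud$points[keep, , drop = FALSE],
                     if (is.null(cloud$colors)) NULL else
                       cloud$colors[keep, , drop = FALSE])
  attr(out, "removed") <- which(!keep)
  out
}
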