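#' Non-uniform box-grid down-sampling to a fixed point budget
#'
#' Octree-style filter: starting from the cloud's bounding box, the
#' occupied box containing the most points is repeatedly split into its
#' eight octants until the number of occupied leaves equals
#' `target_count`, and one representative is emitted per leaf. Dense
#' regions therefore receive fine boxes and sparse regions coarse ones,
#' preserving structure while hitting the budget exactly (ties in "most
#' points" break to the lowest Morton-ordered box, so the result is
#' deterministic; when the final split would overshoot, the largest
#' octants are kept and the remainder pooled so the leaf count lands
#' exactly on the budget).
#'
#' @param cloud A finite [point_cloud()].
#' @param target_count Point budget (default 4096).
#' @param representative `"nearest_to_centroid"` (default; emits the
#'   member point closest to the leaf centroid, so colors stay authentic
#'   samples) or `"centroid"`.
#' @return A `point_cloud` with `min(target_count, count)` points (the
#'   input is returned unchanged, with a warning, when it is already
#'   within budget).
#' @export
nonuniform_grid_sample <- function(cloud, target_count = 4096,
                                   representative = c("nearest_to_centroid",
                                                      "centroid")) {
  stopifnot(inherits(cloud, "point_cloud"), target_count >= 1)
  representative <- match.arg(representative)
  if (cloud$count == 0) {
    warning("empty cloud: nothing to down-sample")
    return(cloud)
  }
  if (!all(is.finite(cloud$points)))
    stop("cloud contains non-finite points; run remove_invalid() first")
  if (cloud$count <= target_count) {
    warning(sprintf("cloud has %d <= %d points: returned unchanged",
                    cloud$count, target_count))
    return(cloud)
  }
  res <- cpp_octree_sample(cloud$points, as.integer(target_count),
                           representative == "nearest_to_centroid")
  if (representative == "nearest_to_centroid") {
    point_cloud(res$points,
                if (is.null(cloud$colors)) NULL else
                  cloud$colors[res$index, , drop = FALSE])
  } else {
    point_cloud(res$points)
  }
}
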