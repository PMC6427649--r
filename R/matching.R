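#' Stereo matching configuration
#'
#' Parameters for the block matchers and semi-global matching. SGM uses a
#' 15x15 window and a 128 px disparity range by default; the SAD/SSD
#' baselines need a much larger 55x55 window to produce usable maps.
#' Penalties `p1 < p2` discourage small and large disparity changes along
#' each aggregation path; costs (and hence penalties) are expressed in
#' 8-bit gray levels of window-mean intensity difference.
#'
#' @param algorithm `"sgm"`, `"sad"` or `"ssd"`.
#' @param window Odd window size in pixels (>= 3). Default 15 for SGM,
#'   55 for SAD/SSD.
#' @param max_disparity Largest disparity searched, pixels (default 128).
#' @param p1,p2 SGM discontinuity penalties, `0 < p1 < p2` (defaults 8
#'   and 32 gray levels).
#' @param num_paths Number of SGM aggregation directions: 2, 4 or 8.
#' @param uniqueness Relative margin by which the best cost must beat the
#'   runner-up (default 0.05); failures are marked invalid.
#' @param lr_tolerance Left-right consistency tolerance in pixels.
#' @return An object of class `matching_config`.
#' @export
matching_config <- function(algorithm = c("sgm", "sad", "ssd"),
                            window = NULL, max_disparity = 128,
                            p1 = 8, p2 = 32, num_paths = 8,
                            uniqueness = 0.05, lr_tolerance = 1) {
  algorithm <- match.arg(algorithm)
  if (is.null(window)) window <- if (algorithm == "sgm") 15L else 55L
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3")
  max_disparity <- as.integer(max_disparity)
  if (max_disparity < 1L) stop("max_disparity must be positive")
  if (!(p2 > p1 && p1 > 0)) stop("penalties must satisfy p2 > p1 > 0")
  if (!num_paths %in% c(2L, 4L, 8L)) stop("num_paths must be 2, 4 or 8")
  structure(list(algorithm = algorithm, window = window,
                 max_disparity = max_disparity, p1 = p1, p2 = p2,
                 num_paths = as.integer(num_paths),
                 uniqueness = uniqueness, lr_tolerance = lr_tolerance),
            class = "matching_config")
}

as_gray255 <- function(img) 255 * rgb_to_gray(img)

new_disparity_map <- function(values, valid, max_disparity) {
  structure(list(values = values, valid = valid,
                 width = ncol(values), height = nrow(values),
                 max_disparity = max_disparity),
            class = "disparity_map")
}

#' @export
print.disparity_map <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("Disparity map %dx%d: %d valid px (%.1f%%), range [%.2f, %.2f]\n",
              x$width, x$height, nv, 100 * nv / (x$width * x$height),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

check_match_inputs <- function(left, right, config) {
  if (!identical(dim(left)[1:2], dim(right)[1:2]))
    stop("left and right images must have the same size")
  if (config$max_disparity >= dim(left)[2])
    stop("max_disparity must be smaller than the image width")
}

#' Windowed matching cost volume
#'
#' Computes `C(p, d)` for every pixel and disparity `0..max_disparity`:
#' the window mean of absolute (SAD) or squared (SSD) gray-level
#' differences between the left pixel and the d-shifted right pixel.
#' Window samples outside either image are excluded and the sum is
#' normalized by the number of contributing samples; candidates with no
#' valid sample are `NA`. Costs are in 8-bit gray levels.
#'
#' @param left,right Rectified images (`[0, 1]` arrays; RGB is converted
#'   to luma).
#' @param config A [matching_config()].
#' @param metric `"sad"` or `"ssd"` (default: the config's algorithm, or
#'   SAD for `"sgm"`).
#' @return `h x w x (max_disparity + 1)` array.
#' @export
cost_volume <- function(left, right, config = matching_config("sad"),
                        metric = NULL) {
  check_match_inputs(left, right, config)
  if (is.null(metric))
    metric <- if (config$algorithm == "ssd") "ssd" else "sad"
  cpp_cost_volume(as_gray255(left), as_gray255(right), config$window,
                  config$max_disparity,
                  match.arg(metric, c("sad", "ssd")) == "ssd")
}

#' Block-matching disparity (SAD/SSD baseline)
#'
#' Winner-take-all over the windowed cost volume with parabolic subpixel
#' refinement; pixels failing the uniqueness or left-right consistency
#' check are invalid (`NA`).
#'
#' @inheritParams cost_volume
#' @return A `disparity_map`.
#' @export
block_match <- function(left, right, config = matching_config("sad")) {
  check_match_inputs(left, right, config)
  res <- cpp_block_match(as_gray255(left), as_gray255(right), config$window,
                         config$max_disparity,
                         config$algorithm == "ssd", config$uniqueness,
                         config$lr_tolerance)
  new_disparity_map(res$values, res$valid, config$max_disparity)
}

#' Semi-global matching disparity
#'
#' Aggregates the windowed SAD cost along `num_paths` 1D scan-line
#' directions with the standard recursion
#' `L_r(p,d) = C(p,d) + min(L_r(p-r,d), L_r(p-r,d+-1)+P1,
#' min_k L_r(p-r,k)+P2) - min_k L_r(p-r,k)`,
#' sums the per-path costs, then selects disparities winner-take-all with
#' subpixel refinement, uniqueness and left-right checks.
#'
#' @inheritParams cost_volume
#' @return A `disparity_map`.
#' @export
sgm_match <- function(left, right, config = matching_config("sgm")) {
  check_match_inputs(left, right, config)
  res <- cpp_sgm_match(as_gray255(left), as_gray255(right), config$window,
                       config$max_disparity, config$p1, config$p2,
                       config$num_paths, config$uniqueness,
                       config$lr_tolerance)
  new_disparity_map(res$values, res$valid, config$max_disparity)
}

#' Semi-global cost aggregation of an explicit cost volume
#'
#' Exposed separately so the aggregation can be checked against
#' independent implementations on small instances. `NA` entries are
#' treated as unmatchable (a very large cost). Path order: left-to-right,
#' right-to-left, top-down, bottom-up, then the four diagonals.
#'
#' @param costvol `h x w x D` array as from [cost_volume()].
#' @param p1,p2 Discontinuity penalties.
#' @param num_paths 2, 4 or 8 directions.
#' @return Aggregated array of the same shape.
#' @export
sgm_aggregate <- function(costvol, p1 = 8, p2 = 32, num_paths = 8) {
  stopifnot(length(dim(costvol)) == 3L)
  cpp_sgm_aggregate(costvol, p1, p2, as.integer(num_paths))
}

#' Export a disparity map as 16-bit fixed point PNG plus validity mask
#'
#' Disparities are stored in 16-bit fixed point at 1/16 px per unit
#' (high byte in the red channel, low byte in the green channel), so
#' the round trip is lossless to 1/32 px. The validity mask is written
#' next to the map as `<path>.mask.png`; metadata (max disparity,
#' scale) in `<path>.json`.
#'
#' @param d A `disparity_map`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_disparity <- function(d, path) {
  stopifnot(inherits(d, "disparity_map"))
  q <- round(d$values * 16)
  q[!d$valid | is.na(q)] <- 0
  if (any(q > 65535)) stop("disparity too large for 16-bit export")
  img <- array(0, c(nrow(q), ncol(q), 3))
  img[, , 1] <- (q %/% 256) / 255
  img[, , 2] <- (q %% 256) / 255
  png::writePNG(img, path)
  png::writePNG(ifelse(d$valid, 1, 0), paste0(path, ".mask.png"))
  jsonlite::write_json(list(max_disparity = d$max_disparity, scale = 16),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a disparity map written by [write_disparity()]
#' @param path PNG path passed to [write_disparity()].
#' @return A `disparity_map`.
#' @export
read_disparity <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  img <- png::readPNG(path)
  q <- round(img[, , 1] * 255) * 256 + round(img[, , 2] * 255)
  valid <- png::readPNG(paste0(path, ".mask.png")) > 0.5
  values <- q / meta$scale
  values[!valid] <- NA
  new_disparity_map(values, valid, meta$max_disparity)
}
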