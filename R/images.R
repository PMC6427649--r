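#' Read an image file
#'
#' Reads a PNG into a numeric array with values in `[0, 1]`: `h x w` for
#' grayscale, `h x w x 3` for RGB (an alpha channel, if present, is
#' dropped).
#'
#' @param path Path to a PNG file.
#' @return Numeric array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  img
}

#' Write an image file
#'
#' @param img Numeric array in `[0, 1]` (`h x w` or `h x w x 3`); values
#'   are clamped.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Convert an RGB image to grayscale
#'
#' ITU-R BT.601 luma: `0.299 R + 0.587 G + 0.114 B`. A matrix input is
#' returned unchanged.
#'
#' @param img `h x w x 3` array or `h x w` matrix in `[0, 1]`.
#' @return `h x w` matrix.
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
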