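#' Point cloud container
#'
#' Unordered 3D points in the left rectified camera frame, millimetres
#' (x right, y down, z away from the camera), with optional 8-bit RGB
#' colors stored as `[0, 1]`.
#'
#' @param points N x 3 numeric matrix (mm).
#' @param colors Optional N x 3 matrix in `[0, 1]`.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, colors = NULL) {
  points <- matrix(as.numeric(points), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (!is.null(colors)) {
    colors <- matrix(as.numeric(colors), ncol = 3)
    if (nrow(colors) != nrow(points))
      stop("colors must have one row per point")
  }
  structure(list(points = points, colors = colors, count = nrow(points)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud: %d points%s\n", x$count,
              if (is.null(x$colors)) "" else " (colored)"))
  if (x$count > 0 && all(is.finite(x$points))) {
    r <- apply(x$points, 2, range)
    cat(sprintf("  x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  invisible(x)
}

#' @export
as.matrix.point_cloud <- function(x, ...) x$points

#' Reproject a disparity map to a dense 3D point cloud
#'
#' For every valid pixel `(u, v)` with disparity `d > 0`:
#' `Z = f B / d`, `X = (u - cx) Z / f`, `Y = (v - cy) Z / f`, in the left
#' rectified camera frame (mm). Invalid or non-positive disparities give
#' non-finite points, so the output always has `width * height` rows in
#' raster order (column-major over rows then columns of the map).
#'
#' @param d A `disparity_map`.
#' @param geom The `rectified_geometry` the disparities refer to (its
#'   shared intrinsics and baseline are used).
#' @param left_rgb Optional rectified left image supplying per-point
#'   color.
#' @return A dense `point_cloud` with `width * height` rows.
#' @export
reproject <- function(d, geom, left_rgb = NULL) {
  stopifnot(inherits(d, "disparity_map"),
            inherits(geom, "rectified_geometry"))
  if (d$width != geom$width || d$height != geom$height)
    stop("disparity map size does not match the rectified geometry")
  f <- geom$intrinsics$fx; B <- geom$baseline
  cx <- geom$intrinsics$cx; cy <- geom$intrinsics$cy
  h <- d$height; w <- d$width
  u <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  v <- matrix(seq_len(h) - 1, h, w)
  dv <- d$values
  dv[!d$valid | dv <= 0] <- NA
  Z <- f * B / dv
  X <- (u - cx) * Z / f
  Y <- (v - cy) * Z / f
  bad <- !is.finite(as.vector(Z))
  pts <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  pts[bad, ] <- NaN
  cols <- NULL
  if (!is.null(left_rgb)) {
    if (is.matrix(left_rgb)) left_rgb <- array(left_rgb, c(h, w, 1))
    cols <- cbind(as.vector(left_rgb[, , 1]),
                  as.vector(left_rgb[, , min(2, dim(left_rgb)[3])]),
                  as.vector(left_rgb[, , min(3, dim(left_rgb)[3])]))
  }
  point_cloud(pts, cols)
}

#' Remove non-finite points from a cloud
#'
#' Keeps exactly the rows whose coordinates are all finite, preserving
#' their order. After this step the cloud is treated as unordered (the
#' raster structure is gone).
#'
#' @param cloud A `point_cloud`.
#' @return A finite `point_cloud`.
#' @export
remove_invalid <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  keep <- rowSums(is.finite(cloud$points)) == 3L
  point_cloud(cloud$points[keep, , drop = FALSE],
              if (is.null(cloud$colors)) NULL else
                cloud$colors[keep, , drop = FALSE])
}
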