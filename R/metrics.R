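# Evaluation: top-view sensitivity of the recognized crop footprint
# against a reference mask, and canopy envelope-box traits.

#' Rasterize a point cloud's top view
#'
#' Orthographic projection along z onto the x-y plane: the cell under
#' each point is set, then a morphological closing (disc of
#' `closing_radius` pixels) bridges the gaps between neighboring sparse
#' points so the footprint is a solid region.
#'
#' @param cloud A finite [point_cloud()].
#' @param resolution Cell size in mm per pixel (default 1).
#' @param origin `c(x, y)` of the mask's lower corner in mm; defaults to
#'   the cloud's own minimum. Supply a shared origin (and `size`) when
#'   two masks must be comparable.
#' @param size Optional `c(nx, ny)` cell counts; defaults to covering
#'   the cloud.
#' @param closing_radius Disc radius in pixels for the closing (default
#'   2; 0 disables it).
#' @param dilate_radius Disc radius in pixels by which occupied cells
#'   are dilated before the closing (default 0). For a down-sampled
#'   cloud each point stands for the whole grid box it was drawn from,
#'   so dilating by about one cell restores the represented footprint;
#'   leave 0 for dense clouds.
#' @return An object of class `top_view_mask`: logical `mask` (rows = y,
#'   cols = x), `origin`, `resolution`.
#' @export
rasterize_top_view <- function(cloud, resolution = 1, origin = NULL,
                               size = NULL, closing_radius = 2,
                               dilate_radius = 0) {
  stopifnot(inherits(cloud, "point_cloud"), resolution > 0)
  pts <- cloud$points
  if (cloud$count == 0) {
    m <- matrix(FALSE, 0, 0)
    return(structure(list(mask = m, origin = c(0, 0),
                          resolution = resolution),
                     class = "top_view_mask"))
  }
  if (is.null(origin)) origin <- c(min(pts[, 1]), min(pts[, 2]))
  ix <- floor((pts[, 1] - origin[1]) / resolution) + 1L
  iy <- floor((pts[, 2] - origin[2]) / resolution) + 1L
  if (is.null(size)) size <- c(max(ix), max(iy))
  keep <- ix >= 1L & ix <= size[1] & iy >= 1L & iy <= size[2]
  m <- matrix(FALSE, size[2], size[1])
  m[cbind(iy[keep], ix[keep])] <- TRUE
  if (dilate_radius > 0 && any(m)) {
    brush <- EBImage::makeBrush(2L * as.integer(dilate_radius) + 1L,
                                shape = "disc")
    m <- EBImage::dilate(m * 1, brush) > 0.5
  }
  if (closing_radius > 0 && any(m)) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L,
                                shape = "disc")
    m <- EBImage::closing(m * 1, brush) > 0.5
  }
  structure(list(mask = m, origin = as.numeric(origin[1:2]),
                 resolution = resolution),
            class = "top_view_mask")
}

#' @export
print.top_view_mask <- function(x, ...) {
  cat(sprintf("Top-view mask %dx%d @ %.2f mm/px, %d set px\n",
              ncol(x$mask), nrow(x$mask), x$resolution, sum(x$mask)))
  invisible(x)
}

#' Sensitivity of a predicted footprint against a reference
#'
#' The fraction of the reference (e.g. manually segmented) crop area
#' recovered by the prediction: `|reference & predicted| / |reference|`,
#' the standard TP / (TP + FN). Masks must share resolution, origin and
#' size. Scalar areas (in pixels) may be supplied instead of masks via
#' `sensitivity_from_areas()`.
#'
#' @param reference,predicted `top_view_mask` objects on the same grid.
#' @return List of class `sensitivity_report`: `reference_area`,
#'   `predicted_area`, `intersection_area` (pixels) and `sensitivity`.
#' @export
sensitivity <- function(reference, predicted) {
  stopifnot(inherits(reference, "top_view_mask"),
            inherits(predicted, "top_view_mask"))
  if (abs(reference$resolution - predicted$resolution) > 1e-9 ||
      max(abs(reference$origin - predicted$origin)) > 1e-9 ||
      !identical(dim(reference$mask), dim(predicted$mask)))
    stop("masks must share resolution, origin and size")
  ra <- sum(reference$mask)
  if (ra == 0) stop("empty reference mask: sensitivity undefined")
  pa <- sum(predicted$mask)
  ia <- sum(reference$mask & predicted$mask)
  structure(list(reference_area = ra, predicted_area = pa,
                 intersection_area = ia, sensitivity = ia / ra),
            class = "sensitivity_report")
}

#' @rdname sensitivity
#' @param reference_area,predicted_area,intersection_area Areas in
#'   pixels.
#' @export
sensitivity_from_areas <- function(reference_area, predicted_area,
                                   intersection_area) {
  stopifnot(reference_area > 0,
            intersection_area <= min(reference_area, predicted_area))
  structure(list(reference_area = reference_area,
                 predicted_area = predicted_area,
                 intersection_area = intersection_area,
                 sensitivity = intersection_area / reference_area),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "Sensitivity %.2f%% (reference %d px, predicted %d px, overlap %d px)\n",
    100 * x$sensitivity, x$reference_area, x$predicted_area,
    x$intersection_area))
  invisible(x)
}

#' Axis-aligned canopy envelope box
#'
#' Min-max extents of the cloud per axis; `volume = length * width *
#' height` with length along x, width along y, height along z.
#'
#' @param x A non-empty [point_cloud()] or N x 3 matrix.
#' @return Object of class `envelope_box` with `length`, `width`,
#'   `height` (mm) and `volume` (mm^3).
#' @export
envelope_box <- function(x) {
  pts <- as_points_matrix(x)
  if (nrow(pts) == 0) stop("empty cloud: no envelope box")
  if (!all(is.finite(pts))) stop("cloud contains non-finite points")
  ext <- unname(apply(pts, 2, function(v) diff(range(v))))
  envelope_box_dims(ext[1], ext[2], ext[3])
}

#' @rdname envelope_box
#' @param length,width,height Box extents in mm (for building a box from
#'   measured dimensions).
#' @export
envelope_box_dims <- function(length, width, height) {
  stopifnot(length >= 0, width >= 0, height >= 0)
  structure(list(length = length, width = width, height = height,
                 volume = length * width * height),
            class = "envelope_box")
}

#' @export
print.envelope_box <- function(x, ...) {
  cat(sprintf("Envelope box %.2f x %.2f x %.2f mm, volume %.3g mm^3\n",
              x$length, x$width, x$height, x$volume))
  invisible(x)
}

#' Theoretical-to-measured envelope volume ratio
#'
#' `100 * theoretical$volume / measured$volume`, the percentage used to
#' compare a stereo-reconstructed canopy box against a hand-measured
#' one.
#'
#' @param theoretical,measured `envelope_box` objects.
#' @return Percentage (numeric scalar).
#' @export
volume_ratio <- function(theoretical, measured) {
  stopifnot(inherits(theoretical, "envelope_box"),
            inherits(measured, "envelope_box"))
  if (measured$volume <= 0) stop("measured volume must be positive")
  100 * theoretical$volume / measured$volume
}

#' Bundled field-study reference tables
#'
#' Plain-text reference measurements from a field study of transplanted
#' brassica seedlings, shipped with the package for evaluation examples:
#'
#' * `cabbage_box_table()`: hand-measured vs stereo-derived canopy
#'   envelope-box dimensions (mm) of three cabbage plants.
#' * `seedling_area_table()`: manually segmented vs algorithmically
#'   recovered top-view pixel areas (and their intersection) of three
#'   broccoli seedling images, with the published sensitivity percent.
#'
#' @return A data frame.
#' @export
cabbage_box_table <- function() {
  read.csv(system.file("extdata", "cabbage_envelope_boxes.csv",
                       package = "seedling3d"))
}

#' @rdname cabbage_box_table
#' @export
seedling_area_table <- function() {
  read.csv(system.file("extdata", "seedling_top_view_areas.csv",
                       package = "seedling3d"))
}
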