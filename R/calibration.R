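#' Camera intrinsic parameters
#'
#' Pinhole intrinsics in pixel units: focal lengths, principal point and
#' (optional) skew, i.e. the upper-triangular camera matrix
#' `K = [fx s cx; 0 fy cy; 0 0 1]`.
#'
#' @param fx,fy Focal lengths in pixels; must be positive.
#' @param cx,cy Principal point in pixels (0-based, origin at the top-left
#'   pixel center, x rightward, y downward).
#' @param skew Axis skew (dimensionless), almost always 0.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' camera_intrinsics(800, 800, 319.5, 239.5)
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, skew = 0) {
  stopifnot(is.numeric(fx), is.numeric(fy), length(fx) == 1L, length(fy) == 1L)
  if (!is.finite(fx) || !is.finite(fy) || fx <= 0 || fy <= 0)
    stop("focal lengths must be positive and finite")
  if (!all(is.finite(c(cx, cy, skew))))
    stop("principal point and skew must be finite")
  structure(list(fx = as.numeric(fx), fy = as.numeric(fy),
                 cx = as.numeric(cx), cy = as.numeric(cy),
                 skew = as.numeric(skew)),
            class = "camera_intrinsics")
}

#' Intrinsics as a 3x3 camera matrix
#' @param k A `camera_intrinsics` object.
#' @return 3x3 numeric matrix.
#' @export
intrinsics_matrix <- function(k) {
  matrix(c(k$fx, 0, 0, k$skew, k$fy, 0, k$cx, k$cy, 1), 3, 3)
}

#' Lens distortion coefficients
#'
#' Brown-Conrady model: radial terms `k1, k2, k3` (k3 optional) and
#' tangential terms `p1, p2`, applied to normalized image coordinates.
#'
#' @param radial Numeric vector of 2 or 3 radial coefficients.
#' @param tangential Numeric vector of 2 tangential coefficients.
#' @return An object of class `distortion_coefficients`.
#' @export
distortion_coefficients <- function(radial = c(0, 0), tangential = c(0, 0)) {
  if (!length(radial) %in% c(2L, 3L))
    stop("radial must have 2 or 3 coefficients")
  if (length(tangential) != 2L)
    stop("tangential must have 2 coefficients")
  if (!all(is.finite(c(radial, tangential))))
    stop("distortion coefficients must be finite")
  if (length(radial) == 2L) radial <- c(radial, 0)
  structure(list(radial = as.numeric(radial),
                 tangential = as.numeric(tangential)),
            class = "distortion_coefficients")
}

#' Stereo rig calibration
#'
#' Bundles the intrinsics and distortion of both cameras with the relative
#' pose of the right camera: a point `x_l` in the left camera frame maps to
#' `x_r = R x_l + T` in the right frame, `T` in millimetres. For a typical
#' side-by-side rig with a 60 mm baseline, `T` is close to `(-60, 0, 0)`.
#'
#' @param left,right `camera_intrinsics` of the two cameras.
#' @param left_distortion,right_distortion `distortion_coefficients`.
#' @param rotation 3x3 orthonormal rotation matrix (det +1, tol 1e-8).
#' @param translation Length-3 numeric vector, millimetres; must be nonzero.
#' @return An object of class `stereo_calibration`.
#' @examples
#' k <- camera_intrinsics(800, 800, 319.5, 239.5)
#' stereo_calibration(k, k, rotation = diag(3), translation = c(-60, 0, 0))
#' @export
stereo_calibration <- function(left, right,
                               left_distortion = distortion_coefficients(),
                               right_distortion = distortion_coefficients(),
                               rotation = diag(3),
                               translation = c(-60, 0, 0)) {
  stopifnot(inherits(left, "camera_intrinsics"),
            inherits(right, "camera_intrinsics"),
            inherits(left_distortion, "distortion_coefficients"),
            inherits(right_distortion, "distortion_coefficients"))
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal (R'R != I beyond 1e-8)")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must have determinant +1 (a reflection is not a rotation)")
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be a finite 3-vector (mm)")
  if (sqrt(sum(translation^2)) <= 0)
    stop("baseline must be positive (zero translation)")
  structure(list(left = left, right = right,
                 left_distortion = left_distortion,
                 right_distortion = right_distortion,
                 rotation = rotation, translation = translation),
            class = "stereo_calibration")
}

#' Baseline length of a stereo rig
#' @param calib A `stereo_calibration`.
#' @return Baseline in millimetres (`||T||`).
#' @export
baseline <- function(calib) {
  stopifnot(inherits(calib, "stereo_calibration"))
  sqrt(sum(calib$translation^2))
}

#' @export
print.stereo_calibration <- function(x, ...) {
  cat("Stereo calibration\n")
  cat(sprintf("  left : f = (%.2f, %.2f) px, c = (%.2f, %.2f) px\n",
              x$left$fx, x$left$fy, x$left$cx, x$left$cy))
  cat(sprintf("  right: f = (%.2f, %.2f) px, c = (%.2f, %.2f) px\n",
              x$right$fx, x$right$fy, x$right$cx, x$right$cy))
  cat(sprintf("  baseline: %.3f mm\n", baseline(x)))
  invisible(x)
}

intrinsics_to_list <- function(k) {
  list(fx = k$fx, fy = k$fy, cx = k$cx, cy = k$cy, skew = k$skew)
}

distortion_to_list <- function(d) {
  list(radial = as.list(d$radial), tangential = as.list(d$tangential))
}

#' Write a stereo calibration to a YAML file
#'
#' The schema stores both intrinsics (pixels), both distortion sets, the
#' 3x3 rotation (row-major) and the translation (mm), with explicit `units`
#' keys. [read_calibration()] reads it back bit-exactly (values are written
#' at full double precision).
#'
#' @param calib A `stereo_calibration`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "stereo_calibration"))
  doc <- list(
    units = list(intrinsics = "pixels", translation = "mm"),
    left = intrinsics_to_list(calib$left),
    right = intrinsics_to_list(calib$right),
    left_distortion = distortion_to_list(calib$left_distortion),
    right_distortion = distortion_to_list(calib$right_distortion),
    rotation = lapply(seq_len(3), function(i) as.list(calib$rotation[i, ])),
    translation = as.list(calib$translation))
  writeLines(yaml::as.yaml(doc, precision = 17L), path)
  invisible(path)
}

yaml_num <- function(doc, field, n = 1L) {
  v <- doc[[field]]
  if (is.null(v)) stop(sprintf("calibration file is missing field '%s'", field))
  v <- suppressWarnings(as.numeric(unlist(v)))
  if (length(v) != n || anyNA(v))
    stop(sprintf("calibration field '%s' must be %d finite number(s)", field, n))
  v
}

read_intrinsics_block <- function(doc, field) {
  b <- doc[[field]]
  if (is.null(b)) stop(sprintf("calibration file is missing field '%s'", field))
  for (f in c("fx", "fy", "cx", "cy"))
    if (is.null(b[[f]]))
      stop(sprintf("calibration file is missing field '%s.%s'", field, f))
  camera_intrinsics(b$fx, b$fy, b$cx, b$cy,
                    skew = if (is.null(b$skew)) 0 else b$skew)
}

read_distortion_block <- function(doc, field) {
  b <- doc[[field]]
  if (is.null(b)) return(distortion_coefficients())
  distortion_coefficients(
    radial = as.numeric(unlist(b$radial)),
    tangential = as.numeric(unlist(b$tangential)))
}

#' Read a stereo calibration from a YAML file
#'
#' Validates the schema written by [write_calibration()]: missing fields
#' raise an error naming the field, and a rotation that is not orthonormal
#' with determinant +1 (tolerance 1e-8) is rejected.
#'
#' @param path Path to a calibration YAML file.
#' @return A validated `stereo_calibration`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  doc <- yaml::read_yaml(path)
  rot <- doc$rotation
  if (is.null(rot)) stop("calibration file is missing field 'rotation'")
  rot <- matrix(suppressWarnings(as.numeric(unlist(rot))), 3, 3, byrow = TRUE)
  if (anyNA(rot)) stop("calibration field 'rotation' must be a 3x3 matrix")
  stereo_calibration(
    left = read_intrinsics_block(doc, "left"),
    right = read_intrinsics_block(doc, "right"),
    left_distortion = read_distortion_block(doc, "left_distortion"),
    right_distortion = read_distortion_block(doc, "right_distortion"),
    rotation = rot,
    translation = yaml_num(doc, "translation", 3L))
}
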