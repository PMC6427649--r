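# Epipolar rectification in the Bouguet style: both cameras are rotated
# onto a shared frame whose x-axis is the baseline, so conjugate points
# fall on the same scan line and stereo matching becomes a 1D search.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

# Forward Brown-Conrady distortion of normalized coordinates (vectors).
distort_normalized <- function(x, y, dist) {
  k <- dist$radial; p <- dist$tangential
  r2 <- x^2 + y^2
  f <- 1 + k[1] * r2 + k[2] * r2^2 + k[3] * r2^3
  xd <- x * f + 2 * p[1] * x * y + p[2] * (r2 + 2 * x^2)
  yd <- y * f + p[1] * (r2 + 2 * y^2) + 2 * p[2] * x * y
  list(x = xd, y = yd)
}

# Iterative inverse of the distortion model (undistortion).
undistort_normalized <- function(xd, yd, dist, iters = 20L) {
  k <- dist$radial; p <- dist$tangential
  x <- xd; y <- yd
  for (i in seq_len(iters)) {
    r2 <- x^2 + y^2
    f <- 1 + k[1] * r2 + k[2] * r2^2 + k[3] * r2^3
    dx <- 2 * p[1] * x * y + p[2] * (r2 + 2 * x^2)
    dy <- p[1] * (r2 + 2 * y^2) + 2 * p[2] * x * y
    x <- (xd - dx) / f
    y <- (yd - dy) / f
  }
  list(x = x, y = y)
}

#' Project 3D points through a camera model
#'
#' Applies the pose `x_cam = R x + T`, perspective division, the
#' Brown-Conrady distortion model and the intrinsics, yielding 0-based
#' pixel coordinates. Points at or behind the camera plane give `NA`.
#'
#' @param points N x 3 matrix (mm).
#' @param intrinsics A [camera_intrinsics()].
#' @param distortion A [distortion_coefficients()].
#' @param rotation,translation Pose of the camera (defaults: identity).
#' @return N x 2 matrix of pixel coordinates `(u, v)`.
#' @export
project_points <- function(points, intrinsics,
                           distortion = distortion_coefficients(),
                           rotation = diag(3), translation = c(0, 0, 0)) {
  points <- matrix(as.numeric(points), ncol = 3)
  pc <- points %*% t(rotation) + matrix(translation, nrow(points), 3,
                                        byrow = TRUE)
  z <- pc[, 3]
  z[z <= 1e-9] <- NA
  d <- distort_normalized(pc[, 1] / z, pc[, 2] / z, distortion)
  u <- intrinsics$fx * d$x + intrinsics$skew * d$y + intrinsics$cx
  v <- intrinsics$fy * d$y + intrinsics$cy
  cbind(u = u, v = v)
}

# Rectified projection of ideal (undistorted) directions for one camera:
# dirs are rows of unit-ish camera-frame vectors; returns (u, v) in the
# rectified raster given rectifying rotation rr and shared (f, cx, cy).
rect_project <- function(dirs, rr, f, cx, cy) {
  dr <- dirs %*% t(rr)
  u <- f * dr[, 1] / dr[, 3] + cx
  v <- f * dr[, 2] / dr[, 3] + cy
  cbind(u, v)
}

# Undistorted camera-frame directions of a set of source pixels.
pixel_directions <- function(u, v, k, dist) {
  yd <- (v - k$cy) / k$fy
  xd <- (u - k$cx - k$skew * yd) / k$fx
  n <- undistort_normalized(xd, yd, dist)
  cbind(n$x, n$y, 1)
}

#' Build the rectification geometry for a stereo rig
#'
#' Computes a shared rectifying rotation whose x-axis is the baseline
#' (with the z-axis averaged between the two cameras), shared intrinsics
#' with the mean focal length, and per-pixel inverse resampling maps for
#' both views. After rectification a 3D point projects to the same row in
#' both views and its disparity is `d = f * B / Z`.
#'
#' The output raster is sized by `policy`:
#' * `"preserve_all"` (default): large enough that every valid source
#'   pixel of either view is retained — the output typically grows (e.g.
#'   a 640x480 rig with distortion and a small relative rotation
#'   rectifies to something like 791x547);
#' * `"crop_valid"`: the inner rectangle covered by both views, so no
#'   black borders remain.
#'
#' @param calib A [stereo_calibration()].
#' @param source_size `c(width, height)` of the source images in pixels.
#' @param policy Output sizing policy, see above.
#' @return An object of class `rectified_geometry` with fields
#'   `intrinsics` (shared), `baseline` (mm), `width`, `height`,
#'   `source_width`, `source_height`, rectifying rotations
#'   `rect_rotation_left/right`, and resampling maps
#'   `map_lx`, `map_ly`, `map_rx`, `map_ry` (output-pixel -> source
#'   coordinates, `NA` where the rectified ray leaves the camera).
#' @export
build_rectification <- function(calib, source_size,
                                policy = c("preserve_all", "crop_valid")) {
  stopifnot(inherits(calib, "stereo_calibration"), length(source_size) == 2L)
  policy <- match.arg(policy)
  w <- as.integer(source_size[1]); h <- as.integer(source_size[2])
  if (baseline(calib) <= 1e-9) stop("degenerate calibration: zero baseline")

  R <- calib$rotation; Tt <- calib$translation
  b_l <- as.numeric(-t(R) %*% Tt)          # right camera center, left frame
  r1 <- unit3(b_l)
  if (r1[1] < 0) r1 <- -r1                 # keep rectified x rightward
  z_r <- as.numeric(t(R) %*% c(0, 0, 1))   # right optical axis, left frame
  z_avg <- unit3(c(0, 0, 1) + z_r)
  r2 <- unit3(cross3(z_avg, r1))
  r3 <- cross3(r1, r2)
  rl <- rbind(r1, r2, r3)                  # left frame -> rectified frame
  rr <- rl %*% t(R)                        # right frame -> rectified frame
  dimnames(rl) <- dimnames(rr) <- NULL

  f_new <- mean(c(calib$left$fx, calib$left$fy, calib$right$fx,
                  calib$right$fy))

  # forward-map the source image boundary of both views (principal point
  # still undecided: project with cx = cy = 0)
  bu <- c(seq(0, w - 1), rep(w - 1, h), seq(w - 1, 0), rep(0, h))
  bv <- c(rep(0, w), seq(0, h - 1), rep(h - 1, w), seq(h - 1, 0))
  edge <- function(k, dist, rot) {
    dirs <- pixel_directions(bu, bv, k, dist)
    rect_project(dirs, rot, f_new, 0, 0)
  }
  pl <- edge(calib$left, calib$left_distortion, rl)
  pr <- edge(calib$right, calib$right_distortion, rr)

  if (policy == "preserve_all") {
    u_lo <- min(pl[, 1], pr[, 1]); u_hi <- max(pl[, 1], pr[, 1])
    v_lo <- min(pl[, 2], pr[, 2]); v_hi <- max(pl[, 2], pr[, 2])
  } else {
    seg <- function(p) {
      i_top <- seq_len(w); i_right <- w + seq_len(h)
      i_bottom <- w + h + seq_len(w); i_left <- 2 * w + h + seq_len(h)
      c(u_lo = max(p[i_left, 1]), u_hi = min(p[i_right, 1]),
        v_lo = max(p[i_top, 2]), v_hi = min(p[i_bottom, 2]))
    }
    sl <- seg(pl); sr <- seg(pr)
    u_lo <- max(sl["u_lo"], sr["u_lo"]); u_hi <- min(sl["u_hi"], sr["u_hi"])
    v_lo <- max(sl["v_lo"], sr["v_lo"]); v_hi <- min(sl["v_hi"], sr["v_hi"])
    if (u_hi <= u_lo || v_hi <= v_lo)
      stop("crop_valid policy leaves no common valid region")
  }
  width <- as.integer(ceiling(u_hi - u_lo + 1 - 1e-6))
  height <- as.integer(ceiling(v_hi - v_lo + 1 - 1e-6))
  cx_new <- -u_lo
  cy_new <- -v_lo

  # inverse maps: rectified pixel -> source pixel, per view
  uu <- matrix(seq_len(width) - 1, height, width, byrow = TRUE)
  vv <- matrix(seq_len(height) - 1, height, width)
  xr <- (uu - cx_new) / f_new
  yr <- (vv - cy_new) / f_new
  make_map <- function(k, dist, rot) {
    dirs <- cbind(as.vector(xr), as.vector(yr), 1)
    dc <- dirs %*% rot                     # = t(rot) applied to each row
    bad <- dc[, 3] <= 1e-9
    xn <- dc[, 1] / dc[, 3]; yn <- dc[, 2] / dc[, 3]
    dd <- distort_normalized(xn, yn, dist)
    mu <- k$fx * dd$x + k$skew * dd$y + k$cx
    mv <- k$fy * dd$y + k$cy
    mu[bad] <- NA; mv[bad] <- NA
    list(x = matrix(mu, height, width), y = matrix(mv, height, width))
  }
  ml <- make_map(calib$left, calib$left_distortion, rl)
  mr <- make_map(calib$right, calib$right_distortion, rr)

  structure(list(
    intrinsics = camera_intrinsics(f_new, f_new, cx_new, cy_new),
    baseline = baseline(calib),
    width = width, height = height,
    source_width = w, source_height = h,
    rect_rotation_left = rl, rect_rotation_right = rr,
    map_lx = ml$x, map_ly = ml$y, map_rx = mr$x, map_ry = mr$y,
    policy = policy), class = "rectified_geometry")
}

#' @export
print.rectified_geometry <- function(x, ...) {
  cat(sprintf(
    "Rectified geometry: %dx%d -> %dx%d (%s), f = %.2f px, baseline = %.2f mm\n",
    x$source_width, x$source_height, x$width, x$height, x$policy,
    x$intrinsics$fx, x$baseline))
  invisible(x)
}

#' Project 3D points into the rectified rasters
#'
#' Maps points given in the (original) left camera frame into the left or
#' right rectified image. Useful for checking the epipolar property: the
#' two views of the same point share a row.
#'
#' @param geom A `rectified_geometry`.
#' @param calib The [stereo_calibration()] the geometry was built from
#'   (needed for the right camera's pose).
#' @param points N x 3 matrix in the left camera frame (mm).
#' @param view `"left"` or `"right"`.
#' @return N x 2 matrix of rectified pixel coordinates.
#' @export
rectified_projection <- function(geom, calib, points,
                                 view = c("left", "right")) {
  view <- match.arg(view)
  points <- matrix(as.numeric(points), ncol = 3)
  if (view == "right")
    points <- points %*% t(calib$rotation) +
      matrix(calib$translation, nrow(points), 3, byrow = TRUE)
  rot <- if (view == "left") geom$rect_rotation_left else
    geom$rect_rotation_right
  rect_project(points, rot, geom$intrinsics$fx, geom$intrinsics$cx,
               geom$intrinsics$cy)
}

#' Rectify a stereo image pair
#'
#' Resamples both images through the geometry's inverse maps with
#' bilinear interpolation; samples outside the source image are black.
#'
#' @param left,right Images as numeric arrays in `[0, 1]` matching the
#'   geometry's source size.
#' @param geom A `rectified_geometry` from [build_rectification()].
#' @return List with rectified `left` and `right` images.
#' @export
rectify_pair <- function(left, right, geom) {
  stopifnot(inherits(geom, "rectified_geometry"))
  chk <- function(img, nm) {
    d <- dim(img)
    if (d[1] != geom$source_height || d[2] != geom$source_width)
      stop(sprintf("%s image is %dx%d but calibration expects %dx%d",
                   nm, d[2], d[1], geom$source_width, geom$source_height))
  }
  chk(left, "left"); chk(right, "right")
  list(left = cpp_remap_bilinear(left, geom$map_lx, geom$map_ly),
       right = cpp_remap_bilinear(right, geom$map_rx, geom$map_ry))
}
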