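# Shared fixtures, built in code.

ideal_intrinsics <- function(f = 800, w = 640, h = 480)
  camera_intrinsics(f, f, (w - 1) / 2, (h - 1) / 2)

# An already-rectified side-by-side rig (identity rotation, 60 mm
# baseline, no distortion).
ideal_rig <- function(f = 800, w = 640, h = 480) {
  k <- ideal_intrinsics(f, w, h)
  stereo_calibration(k, k, translation = c(-60, 0, 0))
}

# A mildly misaligned rig with distortion on both lenses.
skewed_rig <- function(angle_deg = 2) {
  k <- ideal_intrinsics()
  th <- angle_deg * pi / 180
  ry <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  stereo_calibration(
    k, k,
    left_distortion = distortion_coefficients(c(-0.10, 0.02),
                                              c(1e-4, -2e-4)),
    right_distortion = distortion_coefficients(c(-0.05, 0.01), c(0, 0)),
    rotation = ry, translation = c(-60, 2, 1))
}

# Stereo pair with a known constant integer disparity, cut from one
# noise texture: left x corresponds to right x - shift.
shifted_pair <- function(w = 128, h = 64, shift = 10, seed = 2) {
  withr::with_seed(seed, {
    tex <- matrix(runif(h * (w + 2 * shift + 10)), h)
    list(left = tex[, (shift + 1):(shift + w)],
         right = tex[, (2 * shift + 1):(2 * shift + w)])
  })
}

# Independent brute-force SGM path recursion (reference implementation
# for the aggregation): costvol is h x w x D with NA = unmatchable.
bruteforce_sgm <- function(costvol, p1, p2, num_paths) {
  dims <- dim(costvol)
  h <- dims[1]; w <- dims[2]; D <- dims[3]
  BIG <- 1e6
  C <- costvol
  C[is.na(C)] <- BIG
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
               c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  S <- array(0, dims)
  for (r in seq_len(num_paths)) {
    dx <- dirs[[r]][1]; dy <- dirs[[r]][2]
    L <- array(0, dims)
    xs <- if (dx >= 0) seq_len(w) else rev(seq_len(w))
    ys <- if (dy >= 0) seq_len(h) else rev(seq_len(h))
    # iterate so the predecessor along (dx, dy) is already computed
    for (y in ys) for (x in xs) {
      px <- x - dx; py <- y - dy
      if (px < 1 || px > w || py < 1 || py > h) {
        L[y, x, ] <- C[y, x, ]
      } else {
        lp <- L[py, px, ]
        minp <- min(lp)
        for (d in seq_len(D)) {
          m <- lp[d]
          if (d > 1) m <- min(m, lp[d - 1] + p1)
          if (d < D) m <- min(m, lp[d + 1] + p1)
          m <- min(m, minp + p2)
          L[y, x, d] <- C[y, x, d] + m - minp
        }
      }
    }
    S <- S + L
  }
  S
}

# Labeled two-blob Gaussian mixture sample (ground truth for EM
# parameter recovery).
two_blob_sample <- function(n_per = 2000, sep = 100, sd = 5, seed = 7) {
  withr::with_seed(seed, {
    rbind(matrix(rnorm(3 * n_per, 0, sd), ncol = 3),
          sweep(matrix(rnorm(3 * n_per, 0, sd), ncol = 3), 2,
                c(0, 0, sep), "+"))
  })
}

# The full default-scene pipeline run is expensive (~20 s); render and
# run it once per test session and share it across files.
.scene_cache <- new.env(parent = emptyenv())
default_scene_run <- function() {
  if (is.null(.scene_cache$run)) {
    spec <- scene_spec()
    scene <- render_stereo_pair(spec)
    result <- run_pipeline(scene$left, scene$right, spec$calib)
    .scene_cache$run <- list(spec = spec, scene = scene, result = result)
  }
  .scene_cache$run
}

# A small fast disc-canopy scene (no lobes, nadir view) for geometric
# closed-form checks.
disc_scene_spec <- function(...) {
  k <- camera_intrinsics(400, 400, 159.5, 119.5)
  defaults <- list(
    plant_radius = 50, plant_lobes = 0, camera_tilt_deg = 0,
    plant_leaf_amp = 0, soil_roughness = 0, soil_undulation = 0,
    furrow_amplitude = 0, weed_count = 4,
    calib = stereo_calibration(k, k, translation = c(-60, 0, 0)),
    image_size = c(320, 240))
  do.call(scene_spec, utils::modifyList(defaults, list(...)))
}
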