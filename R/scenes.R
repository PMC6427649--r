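# Synthetic field scenes with exact ground truth: a textured soil plane
# 500-2000 mm below a downward-looking rectified stereo rig (60 mm
# baseline), one raised hemispherical crop canopy and scattered lower
# weed bumps. Both views sample the same world-anchored texture, so the
# rendered pair is geometrically consistent with the recorded per-pixel
# disparity d = f B / Z.

#' Specify a synthetic field scene
#'
#' @param ground_depth Soil plane distance from the camera, mm (default
#'   800; the rig's working distance is 500-2000 mm).
#' @param plant_center `c(x, y)` of the seedling on the soil plane, mm.
#' @param plant_radius Canopy radius, mm (default 90, a recently
#'   transplanted seedling whose crown covers roughly 8-9% of the
#'   image at the default working distance).
#' @param plant_height Canopy height above soil, mm (default 180;
#'   field-measured canopies run roughly 150-230 mm).
#' @param plant_rim_frac Height of the canopy edge as a fraction of
#'   `plant_height` (default 0.7). A transplanted seedling's rosette is
#'   a roughly flat-topped leaf crown hanging above the soil rather
#'   than a bump tapering into it, so the canopy edge is a depth
#'   discontinuity; this produces the occlusion ring ("black
#'   boundary") around the crop in the reconstructed cloud. The crown
#'   surface is further modulated by leaf-scale (50-100 mm) height
#'   variation (amplitude `plant_leaf_amp` as a fraction of the local
#'   canopy height), emulating interleaved leaves.
#' @param plant_leaf_amp Leaf-scale height modulation amplitude as a
#'   fraction of local canopy height (default 0.35).
#' @param plant_lobes Number of leaves in the rosette (default 6): the
#'   canopy footprint is a star of this many petals rather than a
#'   filled disc, so its top-view point density peaks at the plant
#'   center and decays outward, as for a real rosette whose outer
#'   leaf tips are separated by visible soil.
#' @param camera_tilt_deg Obliqueness of the handheld rig, degrees
#'   (default 10): the soil plane depth increases along image y by
#'   `tan(tilt)`, as in hand-captured field shots. 0 gives a nadir
#'   view of a fronto-parallel plane.
#' @param soil_roughness Amplitude of clod-scale (60-150 mm) soil
#'   height variation, mm (default 8; 0 gives perfectly flat soil).
#' @param soil_undulation Amplitude of broad (300-600 mm) soil
#'   undulation, mm (default 25), the gentle unevenness of a tilled
#'   bed.
#' @param furrow_amplitude,furrow_wavelength Cultivation ridges:
#'   sinusoidal soil height of this amplitude (mm, default 20) and
#'   wavelength (mm, default 250) running across the image x-axis, as
#'   left by a transplanting bed former. Amplitude 0 disables them.
#' @param weed_count Number of weed bumps (default 8).
#' @param weed_height_range Weed heights, mm (default `c(20, 60)`; must
#'   stay below `plant_height`).
#' @param weed_radius_range Weed footprint radii, mm (default
#'   `c(15, 40)`).
#' @param texture_seed Seed controlling texture, weed placement and
#'   pixel noise (default 0).
#' @param calib A [stereo_calibration()]; default: an ideal rectified
#'   rig, f = 800 px, 60 mm baseline, principal point at the image
#'   center.
#' @param image_size `c(width, height)` in pixels (default 640 x 480).
#' @param noise_sigma Additive Gaussian pixel noise, 8-bit gray levels
#'   (default 2).
#' @param brightness_gain Post-gain with clipping, to emulate
#'   overexposure (default 1 = off).
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(ground_depth = 800, plant_center = c(0, 0),
                       plant_radius = 90, plant_height = 180,
                       plant_rim_frac = 0.7, plant_leaf_amp = 0.35,
                       plant_lobes = 6,
                       camera_tilt_deg = 10, soil_roughness = 8,
                       soil_undulation = 25,
                       furrow_amplitude = 20, furrow_wavelength = 250,
                       weed_count = 24, weed_height_range = c(20, 60),
                       weed_radius_range = c(15, 40), texture_seed = 0,
                       calib = NULL, image_size = c(640, 480),
                       noise_sigma = 2, brightness_gain = 1) {
  if (ground_depth < 500 || ground_depth > 2000)
    stop("ground_depth must lie in the 500-2000 mm working distance")
  if (weed_count > 0 && plant_height > 0 &&
      max(weed_height_range) >= plant_height)
    stop("weeds must stay below the plant canopy (height advantage)")
  if (is.null(calib)) {
    k <- camera_intrinsics(800, 800, (image_size[1] - 1) / 2,
                           (image_size[2] - 1) / 2)
    calib <- stereo_calibration(k, k, translation = c(-60, 0, 0))
  }
  structure(list(ground_depth = ground_depth,
                 plant_center = plant_center,
                 plant_radius = plant_radius, plant_height = plant_height,
                 plant_rim_frac = plant_rim_frac,
                 plant_leaf_amp = plant_leaf_amp,
                 plant_lobes = plant_lobes,
                 camera_tilt_deg = camera_tilt_deg,
                 soil_roughness = soil_roughness,
                 soil_undulation = soil_undulation,
                 furrow_amplitude = furrow_amplitude,
                 furrow_wavelength = furrow_wavelength,
                 weed_count = weed_count,
                 weed_height_range = weed_height_range,
                 weed_radius_range = weed_radius_range,
                 texture_seed = texture_seed, calib = calib,
                 image_size = as.integer(image_size),
                 noise_sigma = noise_sigma,
                 brightness_gain = brightness_gain),
            class = "scene_spec")
}

# Weed bump placement (deterministic given the spec's seed): positions
# uniform over the visible soil, avoiding the canopy footprint.
scene_weeds <- function(spec, world) {
  if (spec$weed_count == 0)
    return(data.frame(x = numeric(), y = numeric(), r = numeric(),
                      h = numeric()))
  with_seed(spec$texture_seed + 1L, {
    n <- 0L; xs <- ys <- rs <- hs <- numeric()
    tries <- 0L
    while (n < spec$weed_count && tries < 1000L) {
      tries <- tries + 1L
      x <- runif(1, world$x[1], world$x[2])
      y <- runif(1, world$y[1], world$y[2])
      r <- runif(1, spec$weed_radius_range[1], spec$weed_radius_range[2])
      if (sqrt(sum((c(x, y) - spec$plant_center)^2)) <
          spec$plant_radius + r + 10) next
      n <- n + 1L
      xs[n] <- x; ys[n] <- y; rs[n] <- r
      hs[n] <- runif(1, spec$weed_height_range[1],
                     spec$weed_height_range[2])
    }
    data.frame(x = xs, y = ys, r = rs, h = hs)
  })
}

# Elevation above the soil plane and class (0 soil, 1 plant, 2 weed) at
# world coordinates (x, y); hemispherical-profile bumps.
scene_elevation <- function(spec, weeds, x, y) {
  # clod-scale soil roughness (zero-mean) is the baseline; plant and
  # weed bumps rise from the local soil surface
  elev <- numeric(length(x))
  if (spec$soil_roughness > 0) {
    st <- scene_texture(spec$texture_seed + 50L, x, y, n1 = 20L, n2 = 8L)
    elev <- elev + spec$soil_roughness * (2 * st - 1)
  }
  if (spec$soil_undulation > 0) {
    ut <- scene_texture(spec$texture_seed + 70L, x, y, n1 = 5L, n2 = 3L)
    elev <- elev + spec$soil_undulation * (2 * ut - 1)
  }
  if (spec$furrow_amplitude > 0) {
    phase <- with_seed(spec$texture_seed + 60L, runif(1, 0, 2 * pi))
    elev <- elev + spec$furrow_amplitude *
      sin(2 * pi * x / spec$furrow_wavelength + phase)
  }
  base <- elev
  cls <- integer(length(x))
  if (spec$plant_height > 0 && spec$plant_radius > 0) {
    dxp <- x - spec$plant_center[1]
    dyp <- y - spec$plant_center[2]
    # star-shaped rosette footprint: the effective radius swells at
    # each leaf lobe and shrinks between leaf tips
    if (spec$plant_lobes > 0) {
      phL <- with_seed(spec$texture_seed + 80L, runif(1, 0, 2 * pi))
      lobe <- cos(spec$plant_lobes / 2 * atan2(dyp, dxp) + phL)^2
      r_eff <- spec$plant_radius * (0.55 + 0.45 * lobe)
    } else {
      r_eff <- spec$plant_radius
    }
    q <- 1 - (dxp^2 + dyp^2) / r_eff^2
    inside <- q > 0
    # elevated leaf crown: a spherical-cap profile clipped below at the
    # rim height (the canopy edge is a depth step over the soil), with
    # leaf-scale roughness so canopy points fill a thick layer rather
    # than a smooth shell -- recognized field canopies span most of the
    # plant height
    profile <- pmax(spec$plant_height * sqrt(pmax(q, 0)),
                    spec$plant_rim_frac * spec$plant_height)
    lt <- scene_texture(spec$texture_seed + 40L, x, y,
                        span = spec$plant_center[1] + c(-200, 200),
                        n1 = 13L, n2 = 7L)
    a <- spec$plant_leaf_amp
    e <- base + ifelse(inside, profile * (1 - a + a * lt), 0)
    upd <- e > elev & inside
    elev[upd] <- e[upd]; cls[upd] <- 1L
  }
  for (i in seq_len(nrow(weeds))) {
    q <- 1 - ((x - weeds$x[i])^2 + (y - weeds$y[i])^2) / weeds$r[i]^2
    e <- base + ifelse(q > 0, weeds$h[i] * sqrt(pmax(q, 0)), 0)
    upd <- e > elev & q > 0
    elev[upd] <- e[upd]; cls[upd] <- 2L
  }
  list(elevation = elev, class = cls)
}

# Seeded band-limited texture over world (x, y): two octaves of bilinear
# value noise anchored to a fixed 1200 mm window.
scene_texture <- function(seed, x, y, span = c(-600, 600),
                          n1 = 96L, n2 = 24L) {
  g1 <- with_seed(seed + 2L, matrix(runif(n1 * n1), n1))
  g2 <- with_seed(seed + 3L, matrix(runif(n2 * n2), n2))
  samp <- function(g, x, y) {
    n <- nrow(g)
    fx <- (x - span[1]) / diff(span) * (n - 1) + 1
    fy <- (y - span[1]) / diff(span) * (n - 1) + 1
    fx <- pmin(pmax(fx, 1), n - 1e-9)
    fy <- pmin(pmax(fy, 1), n - 1e-9)
    x0 <- floor(fx); y0 <- floor(fy)
    wx <- fx - x0; wy <- fy - y0
    g[cbind(y0, x0)] * (1 - wx) * (1 - wy) +
      g[cbind(y0, x0 + 1)] * wx * (1 - wy) +
      g[cbind(y0 + 1, x0)] * (1 - wx) * wy +
      g[cbind(y0 + 1, x0 + 1)] * wx * wy
  }
  0.65 * samp(g1, x, y) + 0.35 * samp(g2, x, y)
}

scene_world_window <- function(spec) {
  k <- spec$calib$left
  w <- spec$image_size[1]; h <- spec$image_size[2]
  zg <- spec$ground_depth
  list(x = c((0 - k$cx) / k$fx, (w - 1 - k$cx) / k$fx) * zg,
       y = c((0 - k$cy) / k$fy, (h - 1 - k$cy) / k$fy) * zg)
}

# Per-pixel surface depth for a camera whose center sits at (x0, 0, 0):
# fixed-point iteration of Z = ground - elevation(X(Z), Y(Z)).
scene_depth_map <- function(spec, weeds, k, x0, w, h, iters = 30L) {
  u <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  v <- matrix(seq_len(h) - 1, h, w)
  # start near the canopy top and damp the update so rays grazing the
  # canopy edge (a depth discontinuity) settle instead of oscillating
  slope <- tan(spec$camera_tilt_deg * pi / 180)
  Z <- matrix(spec$ground_depth - spec$plant_height, h, w)
  for (i in seq_len(iters)) {
    X <- x0 + (u - k$cx) * Z / k$fx
    Y <- (v - k$cy) * Z / k$fy
    el <- scene_elevation(spec, weeds, as.vector(X), as.vector(Y))
    Znew <- matrix(spec$ground_depth + slope * Y - el$elevation, h, w)
    Z <- 0.5 * Z + 0.5 * Znew
  }
  for (i in seq_len(5L)) {
    X <- x0 + (u - k$cx) * Z / k$fx
    Y <- (v - k$cy) * Z / k$fy
    el <- scene_elevation(spec, weeds, as.vector(X), as.vector(Y))
    Z <- matrix(spec$ground_depth + slope * Y - el$elevation, h, w)
  }
  X <- x0 + (u - k$cx) * Z / k$fx
  Y <- (v - k$cy) * Z / k$fy
  el <- scene_elevation(spec, weeds, as.vector(X), as.vector(Y))
  list(Z = Z, X = X, Y = Y, class = matrix(el$class, h, w))
}

scene_shade <- function(spec, weeds, X, Y, cls, seed_off) {
  t <- scene_texture(spec$texture_seed, as.vector(X), as.vector(Y))
  base <- rbind(soil = c(0.45, 0.33, 0.22),
                plant = c(0.15, 0.50, 0.18),
                weed = c(0.22, 0.55, 0.20))
  amp <- 0.55 + 0.9 * t
  img <- array(0, c(nrow(X), ncol(X), 3))
  for (c in 1:3) {
    col <- base[as.vector(cls) + 1L, c]
    img[, , c] <- matrix(col * amp, nrow(X), ncol(X))
  }
  if (spec$noise_sigma > 0)
    img <- img + with_seed(spec$texture_seed + seed_off,
                           array(rnorm(length(img), 0,
                                       spec$noise_sigma / 255), dim(img)))
  img <- img * spec$brightness_gain
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Render a synthetic stereo pair with ground truth
#'
#' Builds the scene height field, intersects every pixel ray of both
#' rectified views with it, shades both views from one world-anchored
#' texture (so correspondences match up to pixel noise), and records the
#' exact left-view disparity `d = f B / Z` and per-pixel class.
#'
#' @param spec A [scene_spec()].
#' @return List: `left`, `right` (RGB arrays in `[0, 1]`), `truth` with
#'   `disparity` (a `disparity_map`), `labels` (`h x w` matrix: 0 soil,
#'   1 plant, 2 weed), `depth` (mm), and `weeds` (placed bumps).
#' @export
render_stereo_pair <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  k <- spec$calib$left
  w <- spec$image_size[1]; h <- spec$image_size[2]
  world <- scene_world_window(spec)
  # canopy must be visible: check its footprint against the soil window
  if (spec$plant_height > 0 &&
      (spec$plant_center[1] - spec$plant_radius < world$x[1] ||
       spec$plant_center[1] + spec$plant_radius > world$x[2] ||
       spec$plant_center[2] - spec$plant_radius < world$y[1] ||
       spec$plant_center[2] + spec$plant_radius > world$y[2]))
    stop("canopy lies (partly) outside the field of view")
  weeds <- scene_weeds(spec, world)
  B <- baseline(spec$calib)
  dl <- scene_depth_map(spec, weeds, k, 0, w, h)
  dr <- scene_depth_map(spec, weeds, k, B, w, h)
  left <- scene_shade(spec, weeds, dl$X, dl$Y, dl$class, 10L)
  right <- scene_shade(spec, weeds, dr$X, dr$Y, dr$class, 11L)
  disp <- new_disparity_map(k$fx * B / dl$Z, matrix(TRUE, h, w),
                            max_disparity = ceiling(max(k$fx * B / dl$Z)))
  list(left = left, right = right,
       truth = list(disparity = disp, labels = dl$class, depth = dl$Z,
                    weeds = weeds))
}

#' Sample a labeled point cloud directly from the scene surfaces
#'
#' Draws `n_points` positions uniformly over the visible soil window
#' (i.e. counts per class are proportional to projected top-view area),
#' lifts them onto the surface and labels them 0 soil / 1 plant /
#' 2 weed. Bypasses the image pipeline for fast clustering tests.
#'
#' @param spec A [scene_spec()].
#' @param n_points Number of points (default 4096).
#' @param seed Seed for the draw (default: the spec's texture seed).
#' @return List: `cloud` (a [point_cloud()] in the left camera frame,
#'   mm), `labels` (integer vector), `weeds`.
#' @export
sample_labeled_cloud <- function(spec, n_points = 4096, seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"), n_points >= 1)
  if (is.null(seed)) seed <- spec$texture_seed
  world <- scene_world_window(spec)
  weeds <- scene_weeds(spec, world)
  with_seed(seed + 4L, {
    x <- runif(n_points, world$x[1], world$x[2])
    y <- runif(n_points, world$y[1], world$y[2])
    el <- scene_elevation(spec, weeds, x, y)
    z <- spec$ground_depth + tan(spec$camera_tilt_deg * pi / 180) * y -
      el$elevation
    list(cloud = point_cloud(cbind(x, y, z)), labels = el$class,
         weeds = weeds)
  })
}

#' Ground-truth crop cloud and top-view mask of a rendered scene
#'
#' Converts the renderer's per-pixel depth and class labels into the
#' world-frame plant point cloud and its rasterized top-view footprint,
#' the reference against which a recognized crop cloud is scored.
#'
#' @param scene The list returned by [render_stereo_pair()].
#' @param spec The [scene_spec()] it was rendered from.
#' @param resolution Raster cell size in mm (default 10, on the order
#'   of the point spacing of a 4096-point down-sampled cloud).
#' @param closing_radius Closing radius in cells (default 2).
#' @param margin Border around the plant footprint, mm (default 20).
#' @return List: `cloud` (plant [point_cloud()]), `mask` (reference
#'   `top_view_mask`), `origin`, `size` (to rasterize predictions on
#'   the same grid).
#' @export
scene_plant_truth <- function(scene, spec, resolution = 10,
                              closing_radius = 2, margin = 20) {
  k <- spec$calib$left
  h <- nrow(scene$truth$depth); w <- ncol(scene$truth$depth)
  u <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  v <- matrix(seq_len(h) - 1, h, w)
  Z <- scene$truth$depth
  X <- (u - k$cx) * Z / k$fx
  Y <- (v - k$cy) * Z / k$fy
  pl <- scene$truth$labels == 1L
  if (!any(pl)) stop("scene contains no plant pixels")
  cloud <- point_cloud(cbind(X[pl], Y[pl], Z[pl]))
  origin <- c(min(X[pl]), min(Y[pl])) - margin
  size <- c(ceiling((max(X[pl]) - origin[1] + margin) / resolution),
            ceiling((max(Y[pl]) - origin[2] + margin) / resolution))
  mask <- rasterize_top_view(cloud, resolution, origin, size,
                             closing_radius)
  list(cloud = cloud, mask = mask, origin = origin, size = size)
}

#' Score a recognized crop cloud against the scene's ground truth
#'
#' Rasterizes the recognized points on the reference grid (dilating
#' each by one cell, the footprint a down-sampled point represents) and
#' computes the top-view sensitivity.
#'
#' @param crop The recognized crop [point_cloud()].
#' @param scene,spec As for [scene_plant_truth()].
#' @param resolution,closing_radius Raster parameters (defaults 10 mm
#'   and 2 cells).
#' @param dilate_radius Dilation for the sparse prediction, cells
#'   (default 1).
#' @return A `sensitivity_report`.
#' @export
scene_crop_sensitivity <- function(crop, scene, spec, resolution = 10,
                                   closing_radius = 2,
                                   dilate_radius = 1) {
  truth <- scene_plant_truth(scene, spec, resolution, closing_radius)
  pred <- rasterize_top_view(crop, resolution, truth$origin, truth$size,
                             closing_radius, dilate_radius)
  sensitivity(truth$mask, pred)
}
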