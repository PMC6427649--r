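test_that("scene specifications enforce the field premises", {
  expect_error(scene_spec(ground_depth = 300), "working distance")
  expect_error(scene_spec(weed_height_range = c(50, 200)),
               "height advantage")
  expect_error(render_stereo_pair(scene_spec(plant_center = c(400, 0))),
               "field of view")
})

test_that("a bare soil plane has constant ground-truth disparity", {
  spec <- disc_scene_spec(plant_height = 0, weed_count = 0)
  sc <- render_stereo_pair(spec)
  d_expected <- 400 * 60 / 800
  expect_equal(max(abs(sc$truth$disparity$values - d_expected)), 0)
  expect_true(all(sc$truth$labels == 0))
})

test_that("canopy and ground disparities follow d = f B / Z", {
  # apex at 650 mm under a 150 mm canopy: d = 800*60/650 = 73.85 px
  k <- camera_intrinsics(800, 800, 319.5, 239.5)
  spec <- scene_spec(plant_height = 150, plant_rim_frac = 0,
                     plant_leaf_amp = 0, plant_lobes = 0,
                     camera_tilt_deg = 0, soil_roughness = 0,
                     soil_undulation = 0, furrow_amplitude = 0,
                     weed_count = 0,
                     calib = stereo_calibration(k, k,
                                                translation = c(-60, 0, 0)))
  sc <- render_stereo_pair(spec)
  # nearest pixel center sits half a pixel off the apex
  expect_equal(max(sc$truth$disparity$values), 800 * 60 / 650,
               tolerance = 2e-5)
  ground <- sc$truth$labels == 0
  expect_equal(unique(round(sc$truth$disparity$values[ground], 6)),
               800 * 60 / 800)
})

test_that("rendering is deterministic and labels cover every pixel", {
  spec <- disc_scene_spec()
  a <- render_stereo_pair(spec)
  b <- render_stereo_pair(spec)
  expect_identical(a$left, b$left)
  expect_identical(a$right, b$right)
  expect_identical(a$truth$disparity$values, b$truth$disparity$values)
  expect_true(all(a$truth$labels %in% 0:2))
  expect_true(all(is.finite(a$truth$depth)))
})

test_that("the rendered pair is stereo-consistent with its ground truth", {
  # matching the rendered images recovers the recorded disparity
  spec <- disc_scene_spec()
  sc <- render_stereo_pair(spec)
  dm <- sgm_match(sc$left, sc$right,
                  matching_config("sgm", window = 11, max_disparity = 48))
  err <- abs(dm$values - sc$truth$disparity$values)
  expect_lt(mean(err[dm$valid], na.rm = TRUE), 1)  # <= 1 px mean error
})

test_that("ground-truth disparity reproduces the height field", {
  spec <- disc_scene_spec()
  sc <- render_stereo_pair(spec)
  g <- build_rectification(spec$calib, c(320, 240))
  pc <- reproject(sc$truth$disparity, g)
  z <- matrix(pc$points[, 3], 240, 320)
  rms <- sqrt(mean((z - sc$truth$depth)^2))
  expect_lt(rms, 2)   # <= 2 mm RMS
})

test_that("overexposure gain brightens and clips the render", {
  spec <- disc_scene_spec(brightness_gain = 2.2)
  sc <- render_stereo_pair(spec)
  base <- render_stereo_pair(disc_scene_spec())
  expect_gt(mean(sc$left), mean(base$left))
  expect_gt(mean(sc$left == 1), 0.01)    # saturated pixels exist
})

test_that("surface-sampled clouds have area-proportional class counts", {
  spec <- scene_spec()
  lc <- sample_labeled_cloud(spec, 4096)
  expect_equal(lc$cloud$count, 4096L)
  expect_length(lc$labels, 4096L)
  # star footprint area: integral of r_eff(theta)^2 / 2 over theta,
  # with r_eff = R (0.55 + 0.45 cos^2(lobes/2 * theta))
  th <- seq(0, 2 * pi, length.out = 1e5)
  frac_lobe <- mean((0.55 + 0.45 * cos(spec$plant_lobes / 2 * th)^2)^2)
  world <- seedling3d:::scene_world_window(spec)
  area_tot <- diff(world$x) * diff(world$y)
  area_plant <- pi * spec$plant_radius^2 * frac_lobe
  p <- area_plant / area_tot
  n_plant <- sum(lc$labels == 1)
  expect_lt(abs(n_plant - 4096 * p), 3 * sqrt(4096 * p * (1 - p)))
  # no weeds requested -> only soil and plant labels
  lc0 <- sample_labeled_cloud(scene_spec(weed_count = 0), 2000)
  expect_true(all(lc0$labels %in% c(0L, 1L)))
})
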