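test_that("matching configuration is validated", {
  expect_error(matching_config("sgm", window = 4), "odd")
  expect_error(matching_config("sgm", p1 = 10, p2 = 5), "p2 > p1")
  expect_equal(matching_config("sgm")$window, 15L)
  expect_equal(matching_config("sad")$window, 55L)
  expect_equal(matching_config("sgm")$max_disparity, 128L)
  img <- matrix(0.5, 10, 20)
  expect_error(cost_volume(img, img, matching_config("sad", window = 5,
                                                     max_disparity = 30)),
               "width")
})

test_that("cost volume is exact on constructed cases", {
  cfg <- matching_config("sad", window = 7, max_disparity = 20)
  pair <- shifted_pair(w = 96, h = 48, shift = 10)
  # identical images: zero cost at d = 0 everywhere
  cv0 <- cost_volume(pair$left, pair$left, cfg)
  expect_equal(max(cv0[, , 1]), 0)
  # textureless images: zero cost at every disparity (ambiguous)
  flat <- matrix(0.5, 48, 96)
  cvf <- cost_volume(flat, flat, cfg)
  expect_equal(max(cvf, na.rm = TRUE), 0)
  # constant shift: arg min over d recovers the shift at interior pixels
  cv <- cost_volume(pair$left, pair$right, cfg)
  interior <- function(m) m[10:39, 40:80]
  am <- apply(cv, c(1, 2), which.min) - 1
  expect_true(all(interior(am) == 10))
  # brute-force oracle for the windowed mean cost at one pixel
  y <- 20; x <- 50; d <- 10; hw <- 3
  win_l <- pair$left[(y - hw):(y + hw), (x - hw):(x + hw)]
  win_r <- pair$right[(y - hw):(y + hw), (x - hw - d):(x + hw - d)]
  expect_equal(cv[y, x, d + 1], mean(abs(win_l - win_r)) * 255,
               tolerance = 1e-9)
  # SSD metric squares the (0-255 scaled) differences
  cvs <- cost_volume(pair$left, pair$right, cfg, metric = "ssd")
  expect_equal(cvs[y, x, d + 1], mean((255 * (win_l - win_r))^2),
               tolerance = 1e-6)
})

test_that("border costs are normalized by the valid sample count", {
  cfg <- matching_config("sad", window = 5, max_disparity = 6)
  pair <- shifted_pair(w = 64, h = 32, shift = 0)
  cv <- cost_volume(pair$left, pair$left, cfg)
  # at d where the whole window falls left of the image: NA
  expect_true(is.na(cv[16, 1, 6]))
  # partial windows still average to 0 for identical images
  expect_equal(cv[1, 1, 1], 0)
})

test_that("block matching recovers a constant shift", {
  pair <- shifted_pair(shift = 10)
  for (alg in c("sad", "ssd")) {
    cfg <- matching_config(alg, window = 7, max_disparity = 30)
    dm <- block_match(pair$left, pair$right, cfg)
    err <- abs(dm$values[10:55, 40:120] - 10)
    expect_gte(mean(err <= 0.5, na.rm = TRUE), 0.95)
  }
})

test_that("textureless input is marked invalid by the uniqueness check", {
  flat <- matrix(0.5, 64, 128)
  dm <- block_match(flat, flat, matching_config("sad", window = 7,
                                                max_disparity = 30))
  expect_gte(mean(!dm$valid), 0.90)
})

test_that("SGM recovers a constant shift almost everywhere", {
  pair <- shifted_pair(shift = 10)
  cfg <- matching_config("sgm", window = 7, max_disparity = 30)
  dm <- sgm_match(pair$left, pair$right, cfg)
  err <- abs(dm$values[10:55, 40:120] - 10)
  expect_gte(mean(err <= 0.5, na.rm = TRUE), 0.98)
})

test_that("SGM aggregation equals the brute-force path recursion", {
  withr::with_seed(11, {
    cv <- array(sample(0:50, 32 * 32 * 8, replace = TRUE), c(32, 32, 8))
  })
  for (np in c(2L, 4L, 8L)) {
    ours <- sgm_aggregate(cv, p1 = 8, p2 = 32, num_paths = np)
    ref <- bruteforce_sgm(cv, p1 = 8, p2 = 32, num_paths = np)
    # integral costs: equality must be exact
    expect_identical(max(abs(ours - ref)), 0)
  }
  # NA (unmatchable) entries are tolerated
  cv[1, 1, 1] <- NA
  ours <- sgm_aggregate(cv, 8, 32, 2)
  ref <- bruteforce_sgm(cv, 8, 32, 2)
  expect_identical(max(abs(ours - ref)), 0)
})

test_that("raising P2 never adds disparity discontinuities", {
  spec <- scene_spec(image_size = c(160, 120), weed_count = 2,
                     plant_radius = 40, texture_seed = 1,
                     calib = stereo_calibration(
                       ideal_intrinsics(200, 160, 120),
                       ideal_intrinsics(200, 160, 120),
                       translation = c(-60, 0, 0)))
  sc <- render_stereo_pair(spec)
  n_disc <- sapply(c(8, 32, 64), function(p2) {
    cfg <- matching_config("sgm", window = 7, max_disparity = 32,
                           p1 = 4, p2 = p2)
    dm <- sgm_match(sc$left, sc$right, cfg)
    dx <- abs(diff(t(dm$values)))
    sum(dx > 1, na.rm = TRUE)
  })
  expect_true(all(diff(n_disc) <= 0))
})

test_that("left-right consistency holds for surviving pixels", {
  pair <- shifted_pair(shift = 6)
  cfg <- matching_config("sgm", window = 7, max_disparity = 20,
                         lr_tolerance = 1)
  dm <- sgm_match(pair$left, pair$right, cfg)
  # survivors must be within tolerance of the true constant disparity
  expect_true(all(abs(dm$values[dm$valid] - 6) <= 1.5))
})

test_that("disparity PNG export round-trips to 1/32 px", {
  withr::with_seed(3, {
    vals <- matrix(runif(40 * 30, 0, 128), 30, 40)
  })
  valid <- matrix(TRUE, 30, 40)
  valid[1:5, 1:5] <- FALSE
  vals[!valid] <- NA
  d <- seedling3d:::new_disparity_map(vals, valid, 128)
  f <- withr::local_tempfile(fileext = ".png")
  write_disparity(d, f)
  d2 <- read_disparity(f)
  expect_identical(d2$valid, valid)
  expect_lte(max(abs(d2$values - vals), na.rm = TRUE), 1 / 32)
  # the full range up to 128 px is representable
  vmax <- seedling3d:::new_disparity_map(matrix(128, 2, 2),
                                         matrix(TRUE, 2, 2), 128)
  write_disparity(vmax, f)
  expect_equal(read_disparity(f)$values, matrix(128, 2, 2))
  # all-invalid map round-trips to an empty mask
  dinv <- seedling3d:::new_disparity_map(matrix(NA_real_, 3, 3),
                                         matrix(FALSE, 3, 3), 16)
  write_disparity(dinv, f)
  expect_false(any(read_disparity(f)$valid))
})
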