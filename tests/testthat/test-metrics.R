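test_that("top-view rasterization counts isolated and filled shapes", {
  # four corner points in their own cells, no closing
  pc <- point_cloud(cbind(c(0, 9, 0, 9), c(0, 0, 9, 9), rep(0, 4)))
  m <- rasterize_top_view(pc, resolution = 3, origin = c(0, 0),
                          size = c(4, 4), closing_radius = 0)
  expect_equal(sum(m$mask), 4)
  # a filled disk of points: area within 5% of pi r^2
  withr::with_seed(25, {
    th <- runif(20000, 0, 2 * pi); rr <- sqrt(runif(20000)) * 50
  })
  disk <- point_cloud(cbind(rr * cos(th), rr * sin(th), rep(0, 20000)))
  md <- rasterize_top_view(disk, resolution = 1, origin = c(-52, -52),
                           size = c(104, 104), closing_radius = 2)
  expect_lt(abs(sum(md$mask) - pi * 50^2) / (pi * 50^2), 0.05)
  # empty cloud: zero-area mask
  me <- rasterize_top_view(point_cloud(matrix(numeric(), 0, 3)))
  expect_equal(sum(me$mask), 0)
})

test_that("dilation restores the footprint a sparse point represents", {
  pc <- point_cloud(cbind(5, 5, 0))
  m0 <- rasterize_top_view(pc, 1, c(0, 0), c(11, 11), closing_radius = 2)
  m1 <- rasterize_top_view(pc, 1, c(0, 0), c(11, 11), closing_radius = 0,
                           dilate_radius = 1)
  expect_equal(sum(m0$mask), 1)   # closing alone cannot thicken a point
  expect_equal(sum(m1$mask), sum(EBImage::makeBrush(3, "disc")))
})

test_that("sensitivity is intersection over reference", {
  mk <- function(mat) structure(list(mask = mat, origin = c(0, 0),
                                     resolution = 1),
                                class = "top_view_mask")
  a <- matrix(FALSE, 10, 10); a[3:6, 3:6] <- TRUE
  expect_equal(sensitivity(mk(a), mk(a))$sensitivity, 1)
  half <- a; half[5:6, ] <- FALSE            # covers half the reference
  expect_equal(sensitivity(mk(a), mk(half))$sensitivity, 0.5)
  # predicted-only pixels outside the reference change nothing
  extra <- half; extra[9:10, 9:10] <- TRUE
  expect_equal(sensitivity(mk(a), mk(extra))$sensitivity, 0.5)
  expect_error(sensitivity(mk(matrix(FALSE, 10, 10)), mk(a)), "empty")
  b <- matrix(FALSE, 5, 5)
  expect_error(sensitivity(mk(a), mk(b)), "share")
})

test_that("the field images' mean sensitivity follows from the areas", {
  tab <- seedling_area_table()
  reports <- Map(sensitivity_from_areas, tab$manual_area_px,
                 tab$theoretical_area_px, tab$intersection_area_px)
  expect_equal(mean(tab$sensitivity_percent), 85.91, tolerance = 1e-8)
  # published row-wise percentages agree with the area quotients for
  # two of three rows under the reference denominator; row a was
  # printed against the algorithmic area instead
  s <- 100 * vapply(reports, `[[`, numeric(1), "sensitivity")
  expect_equal(s[2:3], tab$sensitivity_percent[2:3], tolerance = 0.25)
  expect_equal(100 * tab$intersection_area_px[1] /
                 tab$theoretical_area_px[1],
               tab$sensitivity_percent[1], tolerance = 0.05)
})

test_that("envelope boxes reduce to extents and products", {
  expect_equal(envelope_box(rbind(c(0, 0, 0), c(1, 1, 1)))$volume, 1)
  one <- envelope_box(matrix(c(5, 6, 7), 1))
  expect_equal(one$volume, 0)
  expect_equal(one$length, 0)
  pc <- point_cloud(rbind(c(0, 0, 0), c(264.16, 234.12, 153.98)))
  expect_equal(envelope_box(pc)$volume, 9.52e6, tolerance = 5e-4)
  expect_error(envelope_box(matrix(numeric(), 0, 3)), "empty")
})

test_that("envelope volume never decreases when points are added", {
  withr::with_seed(26, {
    pts <- matrix(rnorm(300), ncol = 3)
  })
  vols <- sapply(seq(10, 100, by = 10), function(n)
    envelope_box(pts[seq_len(n), ])$volume)
  expect_true(all(diff(vols) >= 0))
})

test_that("measured-vs-reconstructed box ratios match the field study", {
  tab <- cabbage_box_table()
  ratios <- mapply(function(i) {
    volume_ratio(
      envelope_box_dims(tab$theoretical_length_mm[i],
                        tab$theoretical_width_mm[i],
                        tab$theoretical_height_mm[i]),
      envelope_box_dims(tab$measured_length_mm[i],
                        tab$measured_width_mm[i],
                        tab$measured_height_mm[i]))
  }, seq_len(nrow(tab)))
  expect_equal(ratios, c(99.09, 83.61, 104.28), tolerance = 0.1 / 83)
  expect_equal(mean(ratios), 95.66, tolerance = 0.1 / 95)
  # identical boxes give exactly 100%
  b <- envelope_box_dims(10, 20, 30)
  expect_equal(volume_ratio(b, b), 100)
  expect_error(volume_ratio(b, envelope_box_dims(0, 0, 0)), "positive")
})

test_that("published box volumes recompute from their printed extents", {
  tab <- cabbage_box_table()
  vol_m <- tab$measured_length_mm * tab$measured_width_mm *
    tab$measured_height_mm
  vol_t <- tab$theoretical_length_mm * tab$theoretical_width_mm *
    tab$theoretical_height_mm
  # printed to 3 significant figures
  expect_equal(signif(vol_m, 3), c(9.61e6, 2.17e7, 1.21e7))
  expect_equal(signif(vol_t, 3), c(9.52e6, 1.82e7, 1.26e7))
})
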