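test_that("an already-rectified rig yields identity maps", {
  g <- build_rectification(ideal_rig(), c(640, 480))
  expect_equal(g$width, 640L)
  expect_equal(g$height, 480L)
  expect_equal(g$map_lx, matrix(0:639, 480, 640, byrow = TRUE),
               tolerance = 1e-10)
  expect_equal(g$map_ly, matrix(0:479, 480, 640), tolerance = 1e-10)
  expect_equal(g$map_rx, g$map_lx, tolerance = 1e-10)
  # resampling through identity maps reproduces the image
  img <- withr::with_seed(1, array(runif(480 * 640 * 3), c(480, 640, 3)))
  out <- rectify_pair(img, img, g)
  expect_equal(out$left, img, tolerance = 1 / 255)
})

test_that("zero baseline is rejected as degenerate", {
  k <- ideal_intrinsics()
  expect_error(stereo_calibration(k, k, translation = c(0, 0, 0)))
})

test_that("epipolar property holds on a misaligned distorted rig", {
  cal <- skewed_rig(2)
  g <- build_rectification(cal, c(640, 480))
  # output grows when all valid source pixels are preserved
  expect_true(g$width > 640 || g$height > 480)
  pts <- withr::with_seed(4, cbind(runif(1000, -200, 200),
                                   runif(1000, -150, 150),
                                   runif(1000, 550, 1100)))
  pl <- rectified_projection(g, cal, pts, "left")
  pr <- rectified_projection(g, cal, pts, "right")
  # >= 99% of true correspondences share a scan line to < 0.5 px
  expect_gte(mean(abs(pl[, 2] - pr[, 2]) < 0.5), 0.99)
  # and disparity equals f B / Z in the rectified frame
  zr <- pts %*% g$rect_rotation_left[3, ]
  d_expected <- g$intrinsics$fx * baseline(cal) / zr
  expect_equal(as.numeric(pl[, 1] - pr[, 1]), as.numeric(d_expected),
               tolerance = 1e-9)
})

test_that("rectification maps invert the forward camera model", {
  cal <- skewed_rig(1)
  g <- build_rectification(cal, c(640, 480))
  pts <- withr::with_seed(5, cbind(runif(50, -100, 100),
                                   runif(50, -80, 80),
                                   runif(50, 650, 950)))
  for (view in c("left", "right")) {
    pr <- rectified_projection(g, cal, pts, view)
    k <- if (view == "left") cal$left else cal$right
    dist <- if (view == "left") cal$left_distortion else
      cal$right_distortion
    src <- if (view == "left")
      project_points(pts, k, dist)
    else
      project_points(pts, k, dist, cal$rotation, cal$translation)
    mx <- if (view == "left") g$map_lx else g$map_rx
    my <- if (view == "left") g$map_ly else g$map_ry
    # bilinear lookup of the inverse map at the forward-projected pixel
    bil <- function(m, u, v) {
      x0 <- floor(u); y0 <- floor(v); fx <- u - x0; fy <- v - y0
      m[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
        m[cbind(y0 + 1, x0 + 2)] * fx * (1 - fy) +
        m[cbind(y0 + 2, x0 + 1)] * (1 - fx) * fy +
        m[cbind(y0 + 2, x0 + 2)] * fx * fy
    }
    expect_lt(max(abs(bil(mx, pr[, 1], pr[, 2]) - src[, 1])), 0.05)
    expect_lt(max(abs(bil(my, pr[, 1], pr[, 2]) - src[, 2])), 0.05)
  }
})

test_that("pure-translation maps shift the image content", {
  img <- withr::with_seed(2, matrix(runif(60 * 80), 60, 80))
  mapx <- matrix(0:79, 60, 80, byrow = TRUE) + 3   # sample 3 px right
  mapy <- matrix(0:59, 60, 80)
  g <- build_rectification(ideal_rig(w = 80, h = 60), c(80, 60))
  g$map_lx <- mapx; g$map_ly <- mapy
  g$map_rx <- mapx; g$map_ry <- mapy
  out <- rectify_pair(img, img, g)
  expect_equal(out$left[, 1:77], img[, 4:80], tolerance = 1e-12)
  expect_true(all(out$left[, 78:80] == 0))   # out-of-source is black
})

test_that("straight world lines stay straight after rectification", {
  cal <- skewed_rig(2)
  g <- build_rectification(cal, c(640, 480))
  # points along a 3D line, projected into the distorted source then
  # traced through the rectification: must be collinear within 0.5 px
  t <- seq(0, 1, length.out = 30)
  p0 <- c(-150, -100, 700); p1 <- c(180, 120, 900)
  pts <- outer(1 - t, p0) + outer(t, p1)
  pr <- rectified_projection(g, cal, pts, "left")
  fitl <- lm(pr[, 2] ~ pr[, 1])
  expect_lt(max(abs(residuals(fitl))), 0.5)
})

test_that("image size mismatches are rejected", {
  g <- build_rectification(ideal_rig(), c(640, 480))
  img <- array(0, c(100, 100, 3))
  expect_error(rectify_pair(img, img, g), "640x480")
})
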