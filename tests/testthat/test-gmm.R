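test_that("a single component reduces to sample moments", {
  x <- withr::with_seed(20, matrix(rnorm(600, 5, 3), ncol = 3))
  fit <- gmm_fit(x, K = 1, seed = 1)
  expect_equal(fit$weights, 1)
  expect_equal(as.numeric(fit$means), colMeans(x), tolerance = 1e-10)
  n <- nrow(x)
  expect_equal(fit$covariances[[1]], cov(x) * (n - 1) / n,
               tolerance = 1e-8)
})

test_that("EM recovers the parameters of two separated blobs", {
  x <- two_blob_sample(n_per = 2000, sep = 100, sd = 5)
  fit <- gmm_fit(x, K = 2, seed = 3)
  ord <- order(fit$means[, 3])
  expect_lt(max(abs(fit$means[ord[1], ] - c(0, 0, 0))), 1)
  expect_lt(max(abs(fit$means[ord[2], ] - c(0, 0, 100))), 1)
  expect_lt(max(abs(fit$weights - 0.5)), 0.02)
})

test_that("responsibilities are row-stochastic and weights sum to one", {
  x <- two_blob_sample(500, 80, 6)
  fit <- gmm_fit(x, K = 4, seed = 5)
  expect_equal(rowSums(fit$responsibilities), rep(1, nrow(x)),
               tolerance = 1e-10)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-10)
})

test_that("the log-likelihood never decreases across iterations", {
  for (seed in 1:3) {
    x <- withr::with_seed(seed + 30,
                          matrix(rnorm(1500, 0, 20), ncol = 3))
    fit <- gmm_fit(x, K = 5, seed = seed)
    expect_true(all(diff(fit$trace) >= -1e-8 * abs(fit$trace[-1])))
  }
})

test_that("one M-step matches brute-force weighted moments exactly", {
  withr::with_seed(40, {
    x <- matrix(rnorm(150), 50, 3)
    gamma <- matrix(runif(50 * 3), 50, 3)
  })
  gamma <- gamma / rowSums(gamma)
  # independent oracle: explicit loops over the update formulas
  K <- 3
  mu_ref <- matrix(0, K, 3)
  sig_ref <- vector("list", K)
  pi_ref <- numeric(K)
  for (k in 1:K) {
    nk <- sum(gamma[, k])
    mu_ref[k, ] <- colSums(gamma[, k] * x) / nk
    s <- matrix(0, 3, 3)
    for (n in 1:50) {
      d <- x[n, ] - mu_ref[k, ]
      s <- s + gamma[n, k] * (d %o% d)
    }
    sig_ref[[k]] <- s / nk
    pi_ref[k] <- nk / 50
  }
  params0 <- list(weights = rep(1 / K, K), means = matrix(0, K, 3),
                  covs = rep(list(diag(3)), K))
  upd <- seedling3d:::em_m_step(x, gamma, params0, cov_floor = 1e-12)
  expect_equal(upd$means, mu_ref, tolerance = 1e-12)
  for (k in 1:K)
    expect_equal(upd$covs[[k]], sig_ref[[k]], tolerance = 1e-12)
  expect_equal(upd$weights, pi_ref, tolerance = 1e-12)
})

test_that("parameter recovery succeeds on a known 3-component mixture", {
  sd_true <- 4
  means_true <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 30))  # >= 5 sigma
  w_true <- c(0.3, 0.3, 0.4)
  ok <- 0L
  for (trial in 1:20) {
    x <- withr::with_seed(trial + 100, {
      comp <- sample.int(3, 2000, replace = TRUE, prob = w_true)
      means_true[comp, ] + matrix(rnorm(6000, 0, sd_true), ncol = 3)
    })
    fit <- gmm_fit(x, K = 3, seed = trial)
    # match fitted to true components by nearest mean
    perm <- apply(fit$means, 1, function(m)
      which.min(colSums((t(means_true) - m)^2)))
    if (length(unique(perm)) == 3 &&
        max(sqrt(rowSums((fit$means - means_true[perm, ])^2))) <
          0.5 * sd_true &&
        max(abs(fit$weights - w_true[perm])) < 0.03)
      ok <- ok + 1L
  }
  expect_gte(ok, 19L)  # >= 95% of 20 seeded trials
})

test_that("component collapse is absorbed by the covariance floor", {
  # many duplicated points invite singular covariances
  x <- rbind(matrix(0, 50, 3), matrix(rnorm(150, 10, 1), ncol = 3))
  expect_no_error(fit <- gmm_fit(x, K = 3, seed = 2, cov_floor = 1e-6))
  for (k in 1:3)
    expect_gte(min(eigen(fit$covariances[[k]],
                         symmetric = TRUE)$values), 1e-6 - 1e-12)
  expect_error(gmm_fit(matrix(rnorm(9), 3, 3), K = 5), "at least K")
})

test_that("fits agree with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  x <- two_blob_sample(800, 90, 5, seed = 9)
  fit <- gmm_fit(x, K = 2, seed = 1)
  ref <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  ordA <- order(fit$means[, 3])
  ordB <- order(ref$parameters$mean[3, ])
  expect_equal(fit$means[ordA, ], t(ref$parameters$mean)[ordB, ],
               tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(fit$weights[ordA], ref$parameters$pro[ordB],
               tolerance = 0.01)
  # and the attained log-likelihood matches
  expect_equal(fit$log_likelihood, as.numeric(ref$loglik),
               tolerance = 1e-3)
})

test_that("model methods behave like a classed fit should", {
  x <- two_blob_sample(300, 100, 5, seed = 8)
  fit <- gmm_fit(x, K = 2, seed = 4)
  expect_output(print(fit), "Gaussian mixture")
  s <- summary(fit)
  expect_s3_class(s, "summary.gmm3d")
  expect_equal(sum(s$table$size), nrow(x))
  cf <- coef(fit)
  expect_named(cf, c("weights", "means", "covariances"))
  ll <- logLik(fit)
  expect_equal(attr(ll, "nobs"), nrow(x))
  expect_equal(attr(ll, "df"), 1 + 2 * 3 + 2 * 6)
  pred <- predict(fit, x[1:10, ])
  expect_identical(pred, fit$labels[1:10])
  gam <- predict(fit, x[1:10, ], type = "responsibility")
  expect_equal(rowSums(gam), rep(1, 10), tolerance = 1e-10)
  sim <- simulate(fit, nsim = 500, seed = 1)
  expect_equal(dim(sim), c(500L, 3L))
  # simulated draws concentrate near the fitted means
  expect_lt(abs(mean(sim[, 3] > 50) - 0.5), 0.1)
})

test_that("the crop component is the one nearest the camera", {
  lc <- sample_labeled_cloud(scene_spec(), 4096)
  fit <- gmm_fit(lc$cloud, K = 10, seed = 0)
  sel <- select_crop_component(fit, lc$cloud)
  # members of the selected component are predominantly true plant
  # (a little soil adjacent to the canopy edge may be absorbed)
  expect_gte(mean(lc$labels[sel$indices] == 1), 0.85)
  # single component: trivially selected
  x <- matrix(rnorm(300), 100, 3)
  f1 <- gmm_fit(x, K = 1)
  expect_identical(select_crop_component(f1)$component, 1L)
})

test_that("k-means baseline partitions separated blobs perfectly", {
  x <- two_blob_sample(500, 120, 5, seed = 10)
  km <- kmeans_baseline(x, 2, seed = 1)
  truth <- rep(1:2, each = 500)
  agree <- max(mean(km$labels == truth), mean(km$labels == 3 - truth))
  expect_equal(agree, 1)
  km2 <- kmeans_baseline(x, 2, seed = 1)
  expect_identical(km$labels, km2$labels)   # seeded determinism
  km1 <- kmeans_baseline(x, 1)
  expect_equal(as.numeric(km1$centers), colMeans(x), tolerance = 1e-9)
})

test_that("crop weight is stable across repeated seeded fits", {
  # the reconstructed sparse cloud of the default field scene
  sp <- default_scene_run()$result$sparse
  st <- pi_stability(sp, K = 10, repeats = 10, seed = 1)
  expect_length(st$pi, 10)
  expect_lt(st$sd, 5e-3)
  # identical seeds give identical fits, hence zero spread
  st0 <- pi_stability(sp, K = 10, seeds = c(7, 7))
  expect_identical(st0$sd, 0)
  # a trivially separated mixture pins the weight
  x <- two_blob_sample(1000, 150, 4, seed = 11)
  st2 <- pi_stability(x, K = 2, repeats = 5, seed = 1)
  expect_lt(st2$sd, 1e-6)
})
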