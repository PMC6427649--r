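# Gaussian mixture clustering of the down-sampled cloud. The mixture
# p(x) = sum_k pi_k N(x | mu_k, Sigma_k) is fitted by EM on the 3D
# coordinates; the crop is then the component nearest the downward-looking
# camera (height advantage of the transplanted seedling).

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# log N(x | mu, Sigma) for all rows of x, via the Cholesky factor.
log_gauss <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- chol(sigma)
  xc <- sweep(x, 2, mu)
  q <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * colSums(q^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

floor_covariance <- function(sigma, floor) {
  sigma <- (sigma + t(sigma)) / 2
  e <- eigen(sigma, symmetric = TRUE)
  e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
}

# k-means++ seeding: first center uniform, then each next center drawn
# with probability proportional to the squared distance to the nearest
# chosen center.
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(0, K, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1, ] <- x[idx, ]
  if (K > 1) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (k in 2:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1L, prob = p)
      centers[k, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[k, ])^2))
    }
  }
  centers
}

as_points_matrix <- function(x) {
  if (inherits(x, "point_cloud")) x$points
  else matrix(as.numeric(as.matrix(x)), ncol = ncol(as.matrix(x)))
}

#' Fit a Gaussian mixture model to a point cloud by EM
#'
#' Alternates the E-step (responsibilities by Bayes' rule,
#' `gamma_nk = pi_k N(x_n | mu_k, Sigma_k) / sum_j pi_j N(x_n | ...)`)
#' with the M-step (weighted moment updates of `mu_k`, `Sigma_k`,
#' `pi_k`) until the relative change of the log-likelihood
#' `ln p(X) = sum_n ln sum_k pi_k N(x_n | mu_k, Sigma_k)` drops below
#' `tol` or `max_iter` is reached. Densities are evaluated in log space
#' and responsibilities via log-sum-exp, so the fit is stable for
#' millimetre-scale clouds. Covariance eigenvalues are floored at
#' `cov_floor`, which absorbs component collapse without error.
#'
#' @param x A [point_cloud()] or numeric matrix (rows = points).
#' @param K Number of mixture components (default 10, which separates a
#'   seedling canopy from soil and weeds in field scenes).
#' @param max_iter Maximum EM iterations (default 200).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param cov_floor Eigenvalue floor for covariances, mm^2 (default 1e-6).
#' @param init `"kmeans++"` (default) or `"random_points"`.
#' @param seed Optional integer seed controlling the initialization (the
#'   RNG state of the session is restored afterwards).
#' @param n_init Number of initializations (default 5): each is run for
#'   `init_iter` EM iterations and the best by log-likelihood is run to
#'   convergence, the standard short-run multi-start strategy that makes
#'   the fit robust to unlucky seeding.
#' @param init_iter Iterations of each short exploratory run (default
#'   30).
#' @return An object of class `gmm3d`: `weights`, `means` (K x d),
#'   `covariances` (list of d x d), `responsibilities` (N x K),
#'   `labels` (max-responsibility assignment), `log_likelihood` (per
#'   iteration trace in `trace`), `iterations`, `converged`, `data`.
#' @seealso [select_crop_component()], [pi_stability()],
#'   [kmeans_baseline()]
#' @examples
#' pts <- rbind(matrix(rnorm(300, 0, 5), ncol = 3),
#'              matrix(rnorm(300, 0, 5) + rep(c(0, 0, 100), each = 100),
#'                     ncol = 3))
#' fit <- gmm_fit(pts, K = 2, seed = 1)
#' summary(fit)
#' @export
gmm_fit <- function(x, K = 10, max_iter = 200, tol = 1e-6,
                    cov_floor = 1e-6, init = c("kmeans++", "random_points"),
                    seed = NULL, n_init = 5L, init_iter = 30L) {
  x <- as_points_matrix(x)
  init <- match.arg(init)
  n <- nrow(x); d <- ncol(x)
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (n < K) stop(sprintf("need at least K = %d points, got %d", K, n))
  stopifnot(tol > 0, cov_floor > 0)

  state <- with_seed(seed, {
    starts <- lapply(seq_len(n_init), function(i) {
      if (init == "kmeans++") kmeanspp_centers(x, K)
      else x[sample.int(n, K), , drop = FALSE]
    })
    # short EM run per start, continue the best by log-likelihood
    cand <- lapply(starts, function(ctr)
      em_run(x, em_init_params(x, ctr, K, cov_floor),
             if (n_init > 1L) min(init_iter, max_iter) else max_iter,
             tol, cov_floor))
    if (n_init > 1L) {
      lls <- vapply(cand, function(s) s$trace[length(s$trace)],
                    numeric(1))
      best <- cand[[which.max(lls)]]
      if (!best$converged && length(best$trace) < max_iter) {
        cont <- em_run(x, best$params, max_iter - length(best$trace) + 1L,
                       tol, cov_floor)
        best <- list(params = cont$params, gamma = cont$gamma,
                     trace = c(best$trace,
                               cont$trace[-1]),
                     converged = cont$converged)
      }
      best
    } else cand[[1]]
  })

  gamma <- state$gamma
  structure(list(
    weights = state$params$weights, means = state$params$means,
    covariances = state$params$covs,
    responsibilities = gamma,
    labels = max.col(gamma, ties.method = "first"),
    log_likelihood = state$trace[length(state$trace)],
    trace = state$trace,
    iterations = length(state$trace), converged = state$converged,
    K = K, n = n, d = d, cov_floor = cov_floor, data = x),
    class = "gmm3d")
}

# Initial mixture parameters from a hard assignment to centers.
em_init_params <- function(x, centers, K, cov_floor) {
  n <- nrow(x)
  d2 <- sapply(seq_len(K), function(k)
    rowSums(sweep(x, 2, centers[k, ])^2))
  gamma <- matrix(0, n, K)
  gamma[cbind(seq_len(n), max.col(-matrix(d2, n, K),
                                  ties.method = "first"))] <- 1
  params <- list(weights = rep(1 / K, K), means = centers,
                 covs = rep(list(floor_covariance(
                   cov(x) + diag(cov_floor, ncol(x)), cov_floor)), K))
  em_m_step(x, gamma, params, cov_floor)
}

# Weighted-moment M-step (the mean / covariance / weight updates).
em_m_step <- function(x, gamma, params, cov_floor) {
  nk <- colSums(gamma)
  K <- length(params$weights)
  for (k in seq_len(K)) {
    if (nk[k] > 1e-10) {
      params$means[k, ] <- colSums(gamma[, k] * x) / nk[k]
      xc <- sweep(x, 2, params$means[k, ])
      params$covs[[k]] <- floor_covariance(
        crossprod(xc * gamma[, k], xc) / nk[k], cov_floor)
    }  # collapsed component: keep previous parameters, weight -> ~0
  }
  params$weights <- pmax(nk, 1e-300) / sum(pmax(nk, 1e-300))
  params
}

# Alternate E- and M-steps from given parameters until the relative
# log-likelihood change drops below tol or max_iter is reached.
em_run <- function(x, params, max_iter, tol, cov_floor) {
  n <- nrow(x)
  K <- length(params$weights)
  trace <- numeric()
  ll_old <- -Inf
  converged <- FALSE
  gamma <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    logp <- sapply(seq_len(K), function(k)
      log(params$weights[k]) +
        log_gauss(x, params$means[k, ], params$covs[[k]]))
    logp <- matrix(logp, n, K)
    lse <- logsumexp_rows(logp)
    ll <- sum(lse)
    trace <- c(trace, ll)
    gamma <- exp(logp - lse)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    params <- em_m_step(x, gamma, params, cov_floor)
  }
  list(params = params, gamma = gamma, trace = trace,
       converged = converged)
}

#' @export
print.gmm3d <- function(x, ...) {
  cat(sprintf(
    "Gaussian mixture (EM): K = %d, n = %d, ln p = %.3f, %d iterations%s\n",
    x$K, x$n, x$log_likelihood, x$iterations,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.gmm3d <- function(object, ...) {
  sizes <- tabulate(object$labels, nbins = object$K)
  mean_z <- vapply(seq_len(object$K), function(k) {
    if (sizes[k] == 0) NA_real_ else
      mean(object$data[object$labels == k, object$d])
  }, numeric(1))
  out <- list(table = data.frame(component = seq_len(object$K),
                                 weight = object$weights, size = sizes,
                                 mean_z = mean_z),
              log_likelihood = object$log_likelihood,
              iterations = object$iterations, converged = object$converged)
  class(out) <- "summary.gmm3d"
  out
}

#' @export
print.summary.gmm3d <- function(x, ...) {
  cat(sprintf("Gaussian mixture: ln p = %.3f after %d iterations\n",
              x$log_likelihood, x$iterations))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.gmm3d <- function(object, ...) {
  list(weights = object$weights, means = object$means,
       covariances = object$covariances)
}

#' @export
logLik.gmm3d <- function(object, ...) {
  d <- object$d
  structure(object$log_likelihood,
            df = (object$K - 1) + object$K * d + object$K * d * (d + 1) / 2,
            nobs = object$n, class = "logLik")
}

#' Predict component membership for new points
#' @param object A fitted `gmm3d`.
#' @param newdata Matrix or [point_cloud()] (default: training data).
#' @param type `"class"` for hard labels, `"responsibility"` for the
#'   N x K posterior matrix.
#' @param ... Unused.
#' @export
predict.gmm3d <- function(object, newdata = NULL,
                          type = c("class", "responsibility"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data else as_points_matrix(newdata)
  logp <- sapply(seq_len(object$K), function(k)
    log(object$weights[k]) +
      log_gauss(x, object$means[k, ], object$covariances[[k]]))
  logp <- matrix(logp, nrow(x), object$K)
  gamma <- exp(logp - logsumexp_rows(logp))
  if (type == "class") max.col(gamma, ties.method = "first") else gamma
}

#' Simulate draws from a fitted mixture
#' @param object A fitted `gmm3d`.
#' @param nsim Number of points to draw (default: the training size).
#' @param seed Optional seed.
#' @param ... Unused.
#' @return `nsim x d` matrix.
#' @export
simulate.gmm3d <- function(object, nsim = object$n, seed = NULL, ...) {
  with_seed(seed, {
    comp <- sample.int(object$K, nsim, replace = TRUE,
                       prob = object$weights)
    out <- matrix(0, nsim, object$d)
    for (k in unique(comp)) {
      idx <- which(comp == k)
      ch <- chol(object$covariances[[k]])
      z <- matrix(rnorm(length(idx) * object$d), length(idx))
      out[idx, ] <- sweep(z %*% ch, 2, object$means[k, ], "+")
    }
    out
  })
}

#' @export
plot.gmm3d <- function(x, dims = c(1, 3), ...) {
  cols <- rainbow(x$K)
  plot(x$data[, dims[1]], x$data[, dims[2]], col = cols[x$labels],
       pch = 20, cex = 0.4,
       xlab = c("x", "y", "z")[dims[1]], ylab = c("x", "y", "z")[dims[2]],
       ...)
  invisible(x)
}

#' Select the crop component of a fitted mixture
#'
#' Transplanted seedlings stand taller than soil and weeds, so with a
#' downward-looking camera the crop is the cluster closest to the camera:
#' the component whose member points have the smallest mean z. Empty
#' components are excluded; ties break to the lower component index.
#'
#' @param model A fitted [gmm_fit()] object.
#' @param cloud Optional [point_cloud()] the model was fitted to (so the
#'   returned members carry colors); defaults to the training
#'   coordinates.
#' @param rule `"lowest_mean_z"` (default) or `"largest_weight"`.
#' @return List with `component` (index), `points` (member
#'   `point_cloud`), `indices` (member rows), `weight` (its `pi_k`).
#' @export
select_crop_component <- function(model, cloud = NULL,
                                  rule = c("lowest_mean_z",
                                           "largest_weight")) {
  stopifnot(inherits(model, "gmm3d"))
  rule <- match.arg(rule)
  sizes <- tabulate(model$labels, nbins = model$K)
  cand <- which(sizes > 0)
  if (length(cand) == 0) stop("all components are empty")
  score <- switch(rule,
    lowest_mean_z = vapply(cand, function(k)
      mean(model$data[model$labels == k, model$d]), numeric(1)),
    largest_weight = -model$weights[cand])
  comp <- cand[which.min(score)]   # which.min: first minimum -> lower index
  idx <- which(model$labels == comp)
  pts <- if (!is.null(cloud)) {
    stopifnot(inherits(cloud, "point_cloud"),
              cloud$count == model$n)
    point_cloud(cloud$points[idx, , drop = FALSE],
                if (is.null(cloud$colors)) NULL else
                  cloud$colors[idx, , drop = FALSE])
  } else {
    point_cloud(model$data[idx, , drop = FALSE])
  }
  list(component = comp, points = pts, indices = idx,
       weight = model$weights[comp])
}

#' K-means clustering baseline
#'
#' Lloyd's algorithm with k-means++ seeding, as a deterministic (given
#' `seed`) baseline against the mixture model: k-means tends to absorb
#' background points into the crop cluster because it ignores cluster
#' shape and weight.
#'
#' @param x Matrix or [point_cloud()].
#' @param K Number of clusters.
#' @param seed Optional integer seed.
#' @param max_iter Maximum Lloyd iterations (default 100).
#' @return List with `labels`, `centers` and the underlying
#'   [stats::kmeans()] fit.
#' @export
kmeans_baseline <- function(x, K, seed = NULL, max_iter = 100) {
  x <- as_points_matrix(x)
  if (nrow(x) < K) stop("need at least K points")
  centers <- with_seed(seed, kmeanspp_centers(x, K))
  centers <- centers[!duplicated(centers), , drop = FALSE]
  fit <- suppressWarnings(
    kmeans(x, centers = centers, iter.max = max_iter, algorithm = "Lloyd"))
  list(labels = fit$cluster, centers = fit$centers, fit = fit)
}

#' Stability of the crop component weight over repeated fits
#'
#' Refits the mixture `repeats` times with different seeds and reports
#' the crop component's mixing weight `pi_k` from each run together with
#' their standard deviation. A stable optimum yields nearly identical
#' weights run to run.
#'
#' @param cloud A [point_cloud()] or matrix.
#' @param K Components (default 10).
#' @param repeats Number of refits (default 10, must be >= 2).
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @param seeds Optional explicit vector of per-run seeds (overrides
#'   `seed`/`repeats` counting; length gives the number of runs).
#' @param ... Passed to [gmm_fit()].
#' @return List with `pi` (per-run crop weights), `sd`, and `components`
#'   (selected index per run).
#' @export
pi_stability <- function(cloud, K = 10, repeats = 10, seed = 1,
                         seeds = NULL, ...) {
  if (is.null(seeds)) seeds <- seed + seq_len(repeats) - 1
  repeats <- length(seeds)
  stopifnot(repeats >= 2)
  pis <- numeric(repeats)
  comps <- integer(repeats)
  for (i in seq_len(repeats)) {
    fit <- gmm_fit(cloud, K = K, seed = seeds[i], ...)
    sel <- select_crop_component(fit)
    pis[i] <- sel$weight
    comps[i] <- sel$component
  }
  list(pi = pis, sd = sd(pis), components = comps)
}
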