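make_toy <- function(seed, n = 60, d = 8, beta = NULL) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * d), n, d))
  if (is.null(beta)) beta <- rep(0, d)
  y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  list(X = X, y = y)
}

fit_ident <- function(X, y, coupling = 0, ...) {
  d <- ncol(X)
  fi <- data.frame(feature = seq_len(d), channel = rep(1, d),
                   time_ms = seq(0, by = 2, length.out = d))
  suppressWarnings(mvlaplace_fit(X, y,
    precision = build_precision(coupling_spec(fi, coupling = coupling)), ...))
}

test_that("fitting pure noise gives small coefficients and a flat importance profile", {
  toy <- make_toy(1, n = 80, d = 10)
  fit <- fit_ident(toy$X, toy$y)
  expect_lt(max(abs(fit$coef_mean)), 0.6)
  ratio <- max(fit$aux_variance / fit$aux_prior_variance) /
           min(fit$aux_variance / fit$aux_prior_variance)
  expect_lt(ratio, 4)  # declared uniformity bound for null data
})

test_that("the informative feature receives the larger auxiliary variance", {
  set.seed(2)
  n <- 120
  X <- scale(matrix(rnorm(n * 2), n, 2))
  y <- rbinom(n, 1, plogis(2.5 * X[, 1]))
  fit <- fit_ident(X, y)
  expect_gt(fit$aux_variance[1], fit$aux_variance[2])
  expect_gt(abs(fit$coef_mean[1]), abs(fit$coef_mean[2]))
})

test_that("expectation propagation is bitwise repeatable", {
  toy <- make_toy(3, n = 50, d = 6, beta = c(1, -1, rep(0, 4)))
  f1 <- fit_ident(toy$X, toy$y)
  f2 <- fit_ident(toy$X, toy$y)
  expect_identical(f1$coef_mean, f2$coef_mean)
  expect_identical(f1$aux_variance, f2$aux_variance)
  expect_identical(f1$coef_cov, f2$coef_cov)
})

test_that("invalid inputs are rejected", {
  toy <- make_toy(4, n = 30, d = 3)
  Xbad <- toy$X; Xbad[1, 1] <- NaN
  expect_error(fit_ident(Xbad, toy$y), "NaN")
  expect_error(mvlaplace_fit(toy$X, rep(1, 30)), "two classes")
  fit <- fit_ident(toy$X, toy$y)
  expect_error(predict(fit, matrix(0, 2, 5)), "features")
})

test_that("a degenerate posterior at zero predicts probability one half", {
  toy <- make_toy(5, n = 30, d = 3)
  fit <- fit_ident(toy$X, toy$y)
  fit$coef_mean[] <- 0
  fit$bias <- 0
  fit$coef_cov[] <- 0
  p <- predict(fit, matrix(rnorm(15), 5, 3), type = "prob")
  expect_equal(p, rep(0.5, 5), tolerance = 1e-10)
})

test_that("predictive probabilities match Monte-Carlo integration of the logistic", {
  set.seed(6)
  fit <- fit_ident(make_toy(6, n = 40, d = 1)$X, make_toy(6, n = 40, d = 1)$y)
  fit$coef_mean <- 0.8
  fit$bias <- -0.3
  fit$coef_cov <- diag(c(0.5, 0.2))
  xnew <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  p <- predict(fit, xnew, type = "prob")
  set.seed(7)
  draws <- 1e5
  th <- cbind(rnorm(draws, 0.8, sqrt(0.5)), rnorm(draws, -0.3, sqrt(0.2)))
  p_mc <- vapply(seq_len(9), function(i)
    mean(plogis(th[, 1] * xnew[i] + th[, 2])), 0)
  expect_equal(p, p_mc, tolerance = 0.01)
})

test_that("jointly negating features and coefficients leaves probabilities unchanged", {
  toy <- make_toy(8, n = 40, d = 4, beta = c(1.5, 0, -1, 0))
  fit <- fit_ident(toy$X, toy$y)
  fit$bias <- 0
  xnew <- matrix(rnorm(20), 5, 4)
  p1 <- predict(fit, xnew, type = "prob")
  ## the matching transformation of the posterior: beta -> -beta flips the
  ## sign of the bias-coefficient covariances as well
  d <- length(fit$coef_mean)
  fit$coef_mean <- -fit$coef_mean
  fit$coef_cov[d + 1, 1:d] <- -fit$coef_cov[d + 1, 1:d]
  fit$coef_cov[1:d, d + 1] <- -fit$coef_cov[1:d, d + 1]
  p2 <- predict(fit, -xnew, type = "prob")
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("importance maps reshape auxiliary variances onto the channel x time grid", {
  ep <- simulate_erp(sim_config(n_trials_per_exemplar = 1, seed = 6))
  fm <- extract_features(ep, c(0, 700))
  av <- runif(ncol(fm$X))
  m <- importance_map(av, fm$feature_index, normalize = "none")
  expect_equal(dim(m$values), c(60, 350))
  expect_equal(m$values[3, 7], av[(3 - 1) * 350 + 7])   # channel-major order
  mx <- importance_map(av, fm$feature_index, normalize = "max")
  expect_equal(max(mx$values), 1)
  expect_error(importance_map(av[-1], fm$feature_index, normalize = "none"),
               "feature_index")
})

test_that("stronger coupling smooths the importance profile along time", {
  tv <- function(v) sum(abs(diff(v)))
  res <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 60
    X <- scale(matrix(rnorm(n * 30), n, 30))
    y <- rbinom(n, 1, plogis(drop(X %*% c(rep(1.2, 6), rep(0, 24)))))
    f0 <- fit_ident(X, y, coupling = 0)
    f100 <- fit_ident(X, y, coupling = 100)
    c(tv(f0$aux_variance / f0$aux_prior_variance),
      tv(f100$aux_variance / f100$aux_prior_variance))
  }, c(0, 0))
  expect_true(all(res[2, ] < res[1, ]))
})

test_that("model methods expose the usual summaries", {
  toy <- make_toy(9, n = 50, d = 5, beta = c(2, rep(0, 4)))
  fit <- fit_ident(toy$X, toy$y)
  expect_s3_class(fit, "mvlaplace")
  expect_length(coef(fit), 6)        # bias + 5 coefficients
  expect_named(coef(fit)[1], "(bias)")
  expect_length(fitted(fit), 50)
  expect_true(all(fitted(fit) > 0 & fitted(fit) < 1))
  expect_length(residuals(fit), 50)
  expect_equal(residuals(fit),
               as.numeric(as.integer(fit$y) == 2) - fitted(fit))
  sims <- simulate(fit, nsim = 3, seed = 1, newdata = toy$X)
  expect_equal(dim(sims), c(50, 3))
  expect_true(all(vapply(sims, is.factor, TRUE)))
  out <- capture.output({ print(fit); print(summary(fit)) })
  expect_true(any(grepl("Laplace", out)))
})
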