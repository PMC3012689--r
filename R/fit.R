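#' Control parameters for expectation propagation
#'
#' @param max_iter maximum EP sweeps (default 200).
#' @param tol convergence tolerance on the maximum absolute change of any
#'   site parameter (default 1e-4).
#' @param damping damping factor for parallel site updates in (0, 1].
#' @param n_quad number of quadrature nodes (Gauss-Hermite for the
#'   logistic tilted moments, Gauss-Laguerre for the scale mixture).
#' @param bias_prior_var variance of the broad Gaussian prior on the
#'   unpenalized bias term.
#' @return A list of class `mvlaplace_control`.
#' @export
mvlaplace_control <- function(max_iter = 200, tol = 1e-4, damping = 0.5,
                              n_quad = 40, bias_prior_var = 100) {
  stopifnot(max_iter >= 1, tol > 0, damping > 0, damping <= 1, n_quad >= 8)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 damping = damping, n_quad = as.integer(n_quad),
                 bias_prior_var = bias_prior_var),
            class = "mvlaplace_control")
}

#' Bayesian logistic regression with a multivariate Laplace prior
#'
#' Fits a two-class logistic regression whose coefficients carry a
#' multivariate Laplace prior, expressed as a Gaussian scale mixture:
#' `beta_i | u_i, v_i ~ N(0, u_i^2 + v_i^2)` with `u` and `v` jointly
#' Gaussian with structured precision `J` (see [build_precision()]).
#' Inference is deterministic expectation propagation producing a
#' Gaussian approximation to the posterior over `(beta, bias)` and the
#' posterior variances of the auxiliary variables, which quantify the
#' relative importance of each feature.
#'
#' @param x numeric matrix of standardized features (trials x features)
#'   or a standardized `erp_features` object.
#' @param y binary labels (factor with two levels, or 0/1); taken from
#'   `x` when `x` is an `erp_features`.
#' @param precision a `precision_model`; default is the identity
#'   (independent standard Laplace prior per coefficient).
#' @param control a [mvlaplace_control()].
#' @return An object of class `mvlaplace` with components `coef_mean`,
#'   `bias`, `coef_cov` (joint posterior covariance of coefficients and
#'   bias), `aux_variance`, `levels`, `convergence`
#'   (iterations/converged/max_site_change), `feature_index` (if known),
#'   and the fitted training labels/probabilities.
#' @export
mvlaplace_fit <- function(x, y = NULL, precision = NULL,
                          control = mvlaplace_control()) {
  feature_index <- NULL
  center <- scale_ <- NULL
  if (inherits(x, "erp_features")) {
    if (!x$standardized)
      stop("features must be standardized before fitting (see standardize())")
    y <- x$y
    feature_index <- x$feature_index
    center <- x$center; scale_ <- x$scale
    x <- x$X
  }
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) stop("NaN or non-finite values in the data")
  if (is.null(y)) stop("labels y are required")
  yf <- if (is.factor(y)) droplevels(y) else factor(y)
  if (nlevels(yf) != 2) stop("y must have exactly two classes")
  sgn <- ifelse(as.integer(yf) == 2, 1, -1)
  d <- ncol(x)
  if (is.null(precision)) {
    fi <- if (is.null(feature_index))
      data.frame(feature = seq_len(d), channel = seq_len(d), time_ms = 0)
    else feature_index
    precision <- build_precision(coupling_spec(fi, coupling = 0))
  }
  stopifnot(inherits(precision, "precision_model"))
  if (precision$spec$n_features != d)
    stop(sprintf("precision model dimension (%d) does not match feature count (%d)",
                 precision$spec$n_features, d))
  gh <- pracma::gaussHermite(control$n_quad)
  gl <- pracma::gaussLaguerre(control$n_quad)
  res <- .ep_mvlaplace(x, sgn, as.matrix(precision$J), control$bias_prior_var,
                       gh$x, gh$w, gl$x, gl$w,
                       control$max_iter, control$tol, control$damping,
                       precision$lambda_min)
  if (!res$converged)
    warning(sprintf(
      "EP did not converge in %d sweeps (max site change %.3g); results returned with diagnostics",
      res$iterations, res$max_site_change))
  m <- drop(res$mean)
  fit <- structure(list(
    coef_mean = m[seq_len(d)],
    bias = m[d + 1],
    coef_var = diag(res$cov)[seq_len(d)],
    coef_cov = res$cov,
    aux_variance = drop(res$aux_variance),
    aux_prior_variance = precision$prior_aux_variance,
    levels = levels(yf),
    n_trials = nrow(x),
    feature_index = feature_index,
    center = center, scale = scale_,
    precision = precision$spec[c("coupling", "lambda", "n_datasets")],
    control = control,
    convergence = list(iterations = res$iterations,
                       converged = res$converged,
                       max_site_change = res$max_site_change),
    y = yf), class = "mvlaplace")
  fit$fitted_prob <- predict(fit, x, type = "prob")
  fit
}

## Gaussian-logistic integral by Gauss-Hermite quadrature:
## E[sigmoid(a)], a ~ N(mu, var)
logistic_gauss <- function(mu, var, n_quad = 40) {
  gh <- pracma::gaussHermite(n_quad)
  A <- outer(sqrt(2 * pmax(var, 0)), gh$x) + mu
  drop(stats::plogis(A) %*% gh$w) / sqrt(pi)
}

#' Predict class probabilities or labels
#'
#' The predictive probability integrates the logistic likelihood over the
#' Gaussian posterior of the linear predictor (Gauss-Hermite quadrature),
#' a deterministic approximation. Trials with probability exactly 0.5 are
#' assigned the first class level.
#'
#' @param object a fitted `mvlaplace` model.
#' @param newdata matrix (trials x features) or `erp_features`. When the
#'   model stores standardization statistics and `newdata` is an
#'   unstandardized `erp_features`, the training statistics are applied.
#' @param type `"prob"` (probability of the second class level),
#'   `"class"`, or `"link"` (posterior mean of the linear predictor).
#' @param ... unused.
#' @export
predict.mvlaplace <- function(object, newdata, type = c("prob", "class", "link"),
                              ...) {
  type <- match.arg(type)
  if (inherits(newdata, "erp_features")) {
    if (!newdata$standardized && !is.null(object$center))
      newdata$X <- sweep(sweep(newdata$X, 2, object$center), 2, object$scale, "/")
    newdata <- newdata$X
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coef_mean))
    stop(sprintf("newdata has %d features; model expects %d",
                 ncol(newdata), length(object$coef_mean)))
  Z <- cbind(newdata, 1)
  mu <- drop(Z %*% c(object$coef_mean, object$bias))
  if (type == "link") return(mu)
  va <- rowSums((Z %*% object$coef_cov) * Z)
  p <- logistic_gauss(mu, va, object$control$n_quad)
  if (type == "prob") return(p)
  factor(object$levels[ifelse(p > 0.5, 2, 1)], levels = object$levels)
}

#' Feature-importance map from auxiliary-variable posterior variances
#'
#' Reshapes the posterior variances of the auxiliary variables onto the
#' channels x time grid. Larger variance marks features that contribute
#' more to classification.
#'
#' @param fit a fitted `mvlaplace` model (or a numeric vector of
#'   auxiliary variances with `feature_index` supplied).
#' @param feature_index data.frame mapping features to (channel, time_ms);
#'   defaults to the one stored in the fit.
#' @param normalize `"prior"` (default; posterior variance divided by the
#'   prior marginal variance of the same auxiliary variable, removing the
#'   structural non-uniformity that graph-boundary nodes of the coupling
#'   chain carry under the prior), `"none"`, or `"max"`.
#' @param prior_variance prior auxiliary variances when `fit` is a plain
#'   vector; taken from the fit otherwise.
#' @return An object of class `importance_map`: list with `values`
#'   (channels x time matrix), `time_ms`, `channels`, `normalization`.
#' @export
importance_map <- function(fit, feature_index = NULL,
                           normalize = c("prior", "none", "max"),
                           prior_variance = NULL) {
  normalize <- match.arg(normalize)
  if (inherits(fit, "mvlaplace")) {
    av <- fit$aux_variance
    if (is.null(feature_index)) feature_index <- fit$feature_index
    if (is.null(prior_variance)) prior_variance <- fit$aux_prior_variance
  } else av <- as.numeric(fit)
  if (is.null(feature_index)) stop("feature_index is required")
  if (normalize == "prior") {
    if (is.null(prior_variance) || anyNA(prior_variance))
      stop("prior auxiliary variances unavailable; use normalize = 'none'")
    av <- av / prior_variance
  }
  nd <- length(av) / nrow(feature_index)
  if (nd != round(nd))
    stop("auxiliary-variance length does not match feature_index")
  if (nd > 1)  # joint multi-dataset fit: average corresponding cells
    av <- rowMeans(matrix(av, ncol = nd))
  chs <- sort(unique(feature_index$channel))
  ts <- sort(unique(feature_index$time_ms))
  vals <- matrix(NA_real_, length(chs), length(ts),
                 dimnames = list(channel = chs, time_ms = ts))
  vals[cbind(match(feature_index$channel, chs),
             match(feature_index$time_ms, ts))] <- av
  if (normalize == "max") vals <- vals / max(vals)
  structure(list(values = vals, time_ms = ts, channels = chs,
                 normalization = normalize), class = "importance_map")
}

#' @export
as.data.frame.importance_map <- function(x, ...) {
  data.frame(channel = rep(x$channels, times = length(x$time_ms)),
             time_ms = rep(x$time_ms, each = length(x$channels)),
             value = as.vector(x$values))
}

#' Write an importance map as plain tabular text
#' @param map an `importance_map`.
#' @param path output path (tab-separated: channel, time_ms, value).
#' @export
write_importance_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.importance_map <- function(x, main = "Importance map", ...) {
  graphics::image(x = x$time_ms, y = x$channels, z = t(x$values),
                  xlab = "time (ms)", ylab = "channel", main = main,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' @export
print.mvlaplace <- function(x, ...) {
  cat(sprintf("Bayesian logistic regression, multivariate Laplace prior (c = %g, lambda = %g)\n",
              x$precision$coupling, x$precision$lambda))
  cat(sprintf("  %d features, %d trials; classes: %s vs %s\n",
              length(x$coef_mean), x$n_trials, x$levels[1], x$levels[2]))
  cat(sprintf("  EP %s in %d sweeps (max site change %.2g)\n",
              if (x$convergence$converged) "converged" else "did NOT converge",
              x$convergence$iterations, x$convergence$max_site_change))
  invisible(x)
}

#' @export
summary.mvlaplace <- function(object, n_top = 10, ...) {
  ord <- order(object$aux_variance, decreasing = TRUE)[seq_len(min(n_top, length(object$coef_mean)))]
  top <- data.frame(feature = ord,
                    coef_mean = object$coef_mean[ord],
                    coef_sd = sqrt(object$coef_var[ord]),
                    aux_variance = object$aux_variance[ord])
  if (!is.null(object$feature_index))
    top <- cbind(top, object$feature_index[ord, c("channel", "time_ms")])
  acc <- mean((object$fitted_prob > 0.5) == (as.integer(object$y) == 2))
  out <- list(fit = object, top = top, train_accuracy = acc)
  class(out) <- "summary.mvlaplace"
  out
}

#' @export
print.summary.mvlaplace <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  training accuracy: %.3f\n", x$train_accuracy))
  cat("  top features by auxiliary variance:\n")
  print(x$top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.mvlaplace <- function(object, ...) {
  c("(bias)" = object$bias,
    stats::setNames(object$coef_mean,
                    paste0("f", seq_along(object$coef_mean))))
}

#' @export
fitted.mvlaplace <- function(object, ...) object$fitted_prob

#' Response residuals of a fitted decoder
#' @param object a fitted `mvlaplace` model.
#' @param ... unused.
#' @return numeric vector `y - p` on the training trials (second class
#'   level coded 1).
#' @export
residuals.mvlaplace <- function(object, ...) {
  as.numeric(as.integer(object$y) == 2) - object$fitted_prob
}

#' Simulate labels from the posterior predictive distribution
#'
#' Draws coefficient vectors from the Gaussian posterior and Bernoulli
#' labels from the implied logistic probabilities.
#'
#' @param object a fitted `mvlaplace` model.
#' @param nsim number of simulated label sets.
#' @param seed RNG seed.
#' @param newdata feature matrix (defaults must be supplied; the training
#'   design is not stored).
#' @param ... unused.
#' @return data.frame with `nsim` columns of factor labels.
#' @export
simulate.mvlaplace <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(newdata, "erp_features")) newdata <- newdata$X
  Z <- cbind(as.matrix(newdata), 1)
  R <- chol(object$coef_cov + diag(1e-10, ncol(Z)))
  out <- replicate(nsim, {
    th <- c(object$coef_mean, object$bias) + drop(crossprod(R, stats::rnorm(ncol(Z))))
    p <- stats::plogis(drop(Z %*% th))
    factor(object$levels[1 + stats::rbinom(nrow(Z), 1, p)], levels = object$levels)
  }, simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
plot.mvlaplace <- function(x, ...) {
  if (is.null(x$feature_index))
    stop("no feature_index stored; use importance_map() with an explicit index")
  plot(importance_map(x), ...)
}
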