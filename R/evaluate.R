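#' Stratified fold assignment
#'
#' Partitions trials into `k` folds, deterministically given `seed`,
#' keeping per-fold class proportions within one trial of the global
#' proportions.
#'
#' @param y factor of class labels.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(y, k = 5, seed = 1) {
  y <- as.factor(y)
  if (k < 2) stop("k must be >= 2")
  if (any(table(y) < k)) stop("need at least k trials per class")
  fold <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Exact binomial significance test against a majority-class baseline
#'
#' Computes the exact one-sided tail probability that a baseline
#' classifier assigning every trial to the most prevalent class would
#' reach at least the observed number of correct trials:
#' `P[Binomial(n_trials, majority_fraction) >= n_correct]`. Significance
#' is Bonferroni-adjusted by `m_comparisons`.
#'
#' @param n_correct observed number of correctly classified trials.
#' @param n_trials number of tested trials.
#' @param majority_fraction baseline success probability, in `[0.5, 1]`.
#' @param alpha significance level (default 0.05).
#' @param m_comparisons Bonferroni correction count (>= 1).
#' @return list with `p_value` and `significant`.
#' @export
binomial_significance <- function(n_correct, n_trials, majority_fraction,
                                  alpha = 0.05, m_comparisons = 1) {
  if (m_comparisons < 1) stop("m_comparisons must be >= 1")
  if (n_correct < 0 || n_correct > n_trials) stop("need 0 <= n_correct <= n_trials")
  if (majority_fraction < 0.5 || majority_fraction > 1)
    stop("majority_fraction must lie in [0.5, 1]")
  p <- stats::pbinom(n_correct - 1, n_trials, majority_fraction,
                     lower.tail = FALSE)
  list(p_value = p, significant = p < alpha / m_comparisons)
}

## shared train/standardize/fit/test step; returns per-trial predictions
fit_and_test <- function(train_fm, test_fm, precision, control) {
  train_fm <- standardize(train_fm)
  test_fm <- apply_standardization(train_fm, test_fm)
  fit <- suppressWarnings(mvlaplace_fit(train_fm, precision = precision,
                                        control = control))
  pred <- predict(fit, test_fm$X, type = "prob")
  cls <- factor(fit$levels[ifelse(pred > 0.5, 2, 1)], levels = fit$levels)
  list(fit = fit, prob = pred, class = cls,
       correct = cls == factor(test_fm$y, levels = fit$levels))
}

make_report <- function(analysis, unit, n, n_correct, alpha = 0.05,
                        m_comparisons = 1, majority = NULL, maps = NULL,
                        predictions = NULL) {
  acc <- n_correct / n
  if (is.null(majority)) majority <- rep(0.5, length(n))
  majority <- pmax(majority, 0.5)
  sig <- mapply(function(k, nn, p0) binomial_significance(k, nn, p0, alpha,
                                                          m_comparisons),
                n_correct, n, majority, SIMPLIFY = FALSE)
  structure(list(
    results = data.frame(analysis = analysis, unit = unit, n = n,
                         accuracy = acc,
                         p_value = vapply(sig, `[[`, 0, "p_value"),
                         significant = vapply(sig, `[[`, TRUE, "significant"),
                         stringsAsFactors = FALSE),
    alpha = alpha, bonferroni_m = m_comparisons,
    maps = maps, predictions = predictions), class = "erp_eval")
}

#' Stratified k-fold cross-validated decoding accuracy
#'
#' Runs the full within-dataset analysis: per fold, features are
#' standardized on the training folds only, the multivariate-Laplace
#' logistic regression is fitted and the held-out fold is predicted.
#'
#' @param features an (unstandardized) `erp_features` object, e.g. from
#'   [extract_features()].
#' @param k folds (default 5).
#' @param seed fold-assignment seed.
#' @param coupling,lambda prior hyperparameters (temporal coupling).
#' @param couple_channels also couple adjacent channels.
#' @param control a [mvlaplace_control()].
#' @param alpha,m_comparisons significance settings for the binomial
#'   test of the pooled accuracy.
#' @return An `erp_eval` report: per-fold rows plus a pooled `"mean"`
#'   row; `maps` holds the across-fold average importance map;
#'   `predictions` the per-trial out-of-fold probabilities.
#' @export
cross_validate <- function(features, k = 5, seed = 1, coupling = 100,
                           lambda = 1, couple_channels = FALSE,
                           control = mvlaplace_control(),
                           alpha = 0.05, m_comparisons = 1) {
  stopifnot(inherits(features, "erp_features"))
  fold <- make_folds(features$y, k, seed)
  spec <- coupling_spec(features$feature_index, coupling = coupling,
                        lambda = lambda, couple_channels = couple_channels)
  prec <- build_precision(spec)
  n <- nrow(features$X)
  prob <- numeric(n); correct <- logical(n)
  av <- 0
  for (f in seq_len(k)) {
    te <- fold == f
    if (length(unique(features$y[!te])) < 2 ||
        length(unique(features$y[te])) < 2)
      stop("a class is absent from a fold; stratification violated")
    r <- fit_and_test(subset_features(features, !te),
                      subset_features(features, te), prec, control)
    prob[te] <- r$prob
    correct[te] <- r$correct
    av <- av + r$fit$aux_variance / k
  }
  n_fold <- tabulate(fold, k)
  k_fold <- vapply(seq_len(k), function(f) sum(correct[fold == f]), 0L)
  ## majority-class baseline computed on the tested trials (per fold / pooled)
  maj_fold <- vapply(seq_len(k),
                     function(f) max(table(features$y[fold == f])) / sum(fold == f), 0)
  maj <- max(table(features$y)) / n
  rep_fold <- make_report(analysis = "cv",
                          unit = c(as.character(seq_len(k)), "mean"),
                          n = c(n_fold, n), n_correct = c(k_fold, sum(correct)),
                          alpha = alpha, m_comparisons = m_comparisons,
                          majority = c(maj_fold, maj))
  rep_fold$maps <- list(importance_map(av, features$feature_index,
                                       prior_variance = prec$prior_aux_variance))
  rep_fold$predictions <- data.frame(trial = seq_len(n), fold = fold,
                                     prob = prob, correct = correct,
                                     label = features$y)
  rep_fold
}

#' Sliding-window decoding
#'
#' Repeats the cross-validated analysis independently on consecutive
#' time windows (default sixteen 40-ms windows from 0 to 640 ms), each
#' with its own importance map.
#'
#' @param epochs an `erp_epochs` object.
#' @param width window width in ms; must divide `end - start`.
#' @param start,end analysis span in ms.
#' @inheritParams cross_validate
#' @return An `erp_eval` report with one row per window (`unit` =
#'   window start in ms) and per-window maps.
#' @export
sliding_window <- function(epochs, width = 40, start = 0, end = 640,
                           k = 5, seed = 1, coupling = 100, lambda = 1,
                           control = mvlaplace_control(),
                           alpha = 0.05, m_comparisons = 1) {
  stopifnot(inherits(epochs, "erp_epochs"))
  if ((end - start) %% width != 0)
    stop("width must divide (end - start)")
  starts <- seq(start, end - width, by = width)
  rows <- NULL; maps <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    fm <- extract_features(epochs, c(starts[w], starts[w] + width))
    if (ncol(fm$X) == 0) stop("window contains zero features")
    cvr <- cross_validate(fm, k = k, seed = seed, coupling = coupling,
                          lambda = lambda, control = control,
                          alpha = alpha, m_comparisons = m_comparisons)
    pooled <- cvr$results[cvr$results$unit == "mean", ]
    pooled$analysis <- "window"
    pooled$unit <- as.character(starts[w])
    rows <- rbind(rows, pooled)
    maps[[w]] <- cvr$maps[[1]]
  }
  structure(list(results = rows, alpha = alpha,
                 bonferroni_m = m_comparisons,
                 maps = stats::setNames(maps, starts), predictions = NULL),
            class = "erp_eval")
}

#' Unseen-exemplar generalization test
#'
#' For each exemplar, trains on the trials of all other exemplars and
#' predicts the semantic category of the held-out exemplar's trials.
#' Above-chance accuracy demonstrates category-level (not item-level)
#' generalization.
#'
#' @param features an (unstandardized) `erp_features` with `exemplar_id`.
#' @param balance balance the *exemplar counts* of the two categories in
#'   the training set by randomly dropping exemplars from the larger one
#'   (default `TRUE`). Holding out one exemplar leaves the categories
#'   asymmetric (e.g. 3 vs 4 exemplars); when trials carry
#'   exemplar-specific signatures, a held-out trial lacks the signatures
#'   of *all* training exemplars, and with unequal exemplar counts that
#'   "missing signature" evidence is asymmetric and pushes the trial
#'   systematically toward the larger category. Equalizing exemplar
#'   counts restores the symmetry of the test.
#' @param seed seed for the balancing subsample.
#' @inheritParams cross_validate
#' @return An `erp_eval` report with one row per exemplar plus a pooled
#'   `"mean"` row.
#' @export
unseen_exemplar <- function(features, coupling = 100, lambda = 1,
                            control = mvlaplace_control(),
                            balance = TRUE, seed = 1,
                            alpha = 0.05, m_comparisons = 1) {
  stopifnot(inherits(features, "erp_features"))
  ex <- levels(droplevels(features$exemplar_id))
  if (length(ex) < 4) stop("need >= 2 exemplars per category")
  spec <- coupling_spec(features$feature_index, coupling = coupling,
                        lambda = lambda)
  prec <- build_precision(spec)
  unit <- character(0); n <- integer(0); n_correct <- integer(0)
  for (e in ex) {
    te <- features$exemplar_id == e
    if (!any(te)) { warning(sprintf("exemplar %s has no trials; skipped", e)); next }
    tr_idx <- which(!te)
    if (balance) {
      set.seed(seed + match(e, ex))
      ex_cat <- tapply(as.character(features$y[tr_idx]),
                       droplevels(features$exemplar_id[tr_idx]),
                       function(v) v[1])
      cnt <- table(ex_cat)
      n_keep <- min(cnt)
      keep_ex <- unlist(lapply(names(cnt), function(cl)
        sample(names(ex_cat)[ex_cat == cl], n_keep)))
      tr_idx <- tr_idx[features$exemplar_id[tr_idx] %in% keep_ex]
    }
    r <- fit_and_test(subset_features(features, tr_idx),
                      subset_features(features, te), prec, control)
    unit <- c(unit, e); n <- c(n, sum(te)); n_correct <- c(n_correct, sum(r$correct))
  }
  make_report("unseen_exemplar", unit = c(unit, "mean"),
              n = c(n, sum(n)), n_correct = c(n_correct, sum(n_correct)),
              alpha = alpha, m_comparisons = m_comparisons)
}

#' Transfer learning across datasets with a coupled prior
#'
#' Fits one joint model over several datasets (e.g. stimulus modalities)
#' sharing a channel x time layout. Each dataset has its own coefficient
#' block; auxiliary variables of corresponding features are coupled
#' across datasets through the multivariate Laplace prior, so the
#' sparsity profile (feature relevance) is shared while coefficients
#' remain dataset-specific. Accuracy is estimated by stratified k-fold
#' cross-validation applied jointly.
#'
#' @param datasets list of `erp_epochs` objects with identical
#'   channel/time grids.
#' @param interval feature interval in ms (half-open).
#' @inheritParams cross_validate
#' @return An `erp_eval` report with one accuracy row per dataset; `maps`
#'   holds the joint (across-dataset average) importance map.
#' @export
transfer_learning <- function(datasets, interval = c(0, 700), k = 5,
                              seed = 1, coupling = 100, lambda = 1,
                              control = mvlaplace_control(),
                              alpha = 0.05, m_comparisons = 1) {
  stopifnot(is.list(datasets), length(datasets) >= 2)
  fms <- lapply(datasets, extract_features, interval = interval)
  fi <- fms[[1]]$feature_index
  for (fm in fms[-1])
    if (!identical(fm$feature_index, fi))
      stop("datasets have mismatched channel/time grids")
  nd <- length(fms)
  d1 <- nrow(fi)
  spec <- coupling_spec(fi, coupling = coupling, lambda = lambda,
                        n_datasets = nd)
  prec <- build_precision(spec)
  folds <- lapply(seq_len(nd), function(b) make_folds(fms[[b]]$y, k, seed + b))
  ns <- vapply(fms, function(f) nrow(f$X), 0L)
  correct <- lapply(ns, logical)
  av <- 0
  for (f in seq_len(k)) {
    ## assemble block-structured joint training and test sets
    tr_list <- list(); te_list <- list()
    for (b in seq_len(nd)) {
      te <- folds[[b]] == f
      tr_fm <- standardize(subset_features(fms[[b]], !te))
      te_fm <- apply_standardization(tr_fm, subset_features(fms[[b]], te))
      pad <- function(X, b) {
        out <- matrix(0, nrow(X), d1 * nd)
        out[, (b - 1) * d1 + seq_len(d1)] <- X
        out
      }
      tr_list[[b]] <- list(X = pad(tr_fm$X, b), y = tr_fm$y)
      te_list[[b]] <- list(X = pad(te_fm$X, b), y = te_fm$y, idx = which(te))
    }
    Xtr <- do.call(rbind, lapply(tr_list, `[[`, "X"))
    ytr <- factor(unlist(lapply(tr_list, function(l) as.character(l$y))),
                  levels = levels(fms[[1]]$y))
    fit <- suppressWarnings(mvlaplace_fit(Xtr, ytr, precision = prec,
                                          control = control))
    av <- av + fit$aux_variance / k
    for (b in seq_len(nd)) {
      cls <- predict(fit, te_list[[b]]$X, type = "class")
      correct[[b]][te_list[[b]]$idx] <-
        cls == factor(te_list[[b]]$y, levels = fit$levels)
    }
  }
  nm <- names(datasets)
  if (is.null(nm)) nm <- paste0("dataset", seq_len(nd))
  rep <- make_report("transfer", unit = nm, n = ns,
                     n_correct = vapply(correct, sum, 0L),
                     alpha = alpha, m_comparisons = m_comparisons)
  rep$maps <- list(importance_map(av, fi,
                                  prior_variance = prec$prior_aux_variance))
  rep
}

#' @export
print.erp_eval <- function(x, ...) {
  cat("Decoding evaluation report\n")
  print(x$results, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an evaluation report as tabular text
#' @param report an `erp_eval` report.
#' @param path output path (tab-separated).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "erp_eval"))
  utils::write.table(report$results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
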