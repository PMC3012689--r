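test_that("stratified folds partition trials and preserve class proportions", {
  y <- factor(rep(c("a", "b"), each = 320))
  fold <- make_folds(y, k = 5, seed = 2)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(as.vector(table(fold)), rep(128, 5))
  for (f in 1:5)
    expect_lte(abs(diff(table(y[fold == f]))), 1)
  ## deterministic given seed
  expect_identical(fold, make_folds(y, 5, seed = 2))
  expect_false(identical(fold, make_folds(y, 5, seed = 3)))
  expect_error(make_folds(factor(rep(c("a", "b"), c(3, 40))), k = 5),
               "at least k")
})

test_that("the exact binomial test matches direct tail summation", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(20:400, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.5, 0.95)
    direct <- sum(dbinom(k:n, n, p0))
    expect_equal(binomial_significance(k, n, p0)$p_value, direct,
                 tolerance = 1e-12)
  }
})

test_that("binomial baseline behaviour and Bonferroni threshold", {
  ## classifier performing exactly at baseline is not significant
  r <- binomial_significance(50, 100, 0.5)
  expect_gte(r$p_value, 0.46)
  expect_false(r$significant)
  r65 <- binomial_significance(65, 100, 0.5)
  expect_equal(r65$p_value, sum(dbinom(65:100, 100, 0.5)), tolerance = 1e-15)
  ## alpha 0.05 over 20 comparisons: per-test threshold 0.0025
  p_between <- binomial_significance(64, 100, 0.5, alpha = 0.05,
                                     m_comparisons = 20)
  expect_false(p_between$significant)         # p ~ 0.0033 > 0.0025
  expect_true(binomial_significance(70, 100, 0.5, 0.05, 20)$significant)
  expect_error(binomial_significance(5, 10, 0.5, m_comparisons = 0), "m_comparisons")
  expect_error(binomial_significance(5, 10, 0.3), "majority_fraction")
})

test_that("reported accuracies equal recomputed per-trial proportions", {
  ep <- tiny_epochs(seed = 13, amp = 5, exemplars = default_exemplars(2))
  r <- cross_validate(extract_features(ep, c(0, 60)), k = 4, seed = 13,
                      control = quick_control())
  pr <- r$predictions
  for (f in 1:4) {
    expect_equal(r$results$accuracy[f], mean(pr$correct[pr$fold == f]))
    expect_equal(r$results$n[f], sum(pr$fold == f))
  }
  expect_equal(pooled_acc(r), mean(pr$correct))
  ## folds are a true partition
  expect_equal(sort(pr$trial), 1:40)
})

test_that("strongly separable data is decoded nearly perfectly", {
  ep <- tiny_epochs(seed = 14, amp = 20, exemplars = default_exemplars(2))
  acc <- pooled_acc(cross_validate(extract_features(ep, c(0, 60)), k = 4,
                                   seed = 14, control = quick_control()))
  expect_gte(acc, 0.95)
})

test_that("label shuffling brings accuracy back to chance", {
  ep <- tiny_epochs(seed = 15, amp = 20, trials = 20,
                    exemplars = default_exemplars(2))
  fm <- extract_features(ep, c(0, 60))
  set.seed(15)
  fm$y <- sample(fm$y)
  acc <- pooled_acc(cross_validate(fm, k = 4, seed = 15,
                                   control = quick_control()))
  expect_lt(abs(acc - 0.5), chance_band(80) + 0.04)
})

test_that("sliding windows tile the analysis span and report one row each", {
  ep <- tiny_epochs(seed = 16, amp = 6, n_channels = 4, epoch_end = 100,
                    trials = 10, exemplars = default_exemplars(2),
                    window = c(40, 60), channels = 2:3)
  r <- sliding_window(ep, width = 20, start = 0, end = 100, k = 4, seed = 16,
                      control = quick_control())
  expect_equal(nrow(r$results), 5)
  expect_equal(r$results$unit, as.character(seq(0, 80, 20)))
  expect_length(r$maps, 5)
  expect_equal(dim(r$maps[[1]]$values), c(4, 10))
  ## the window containing the injected effect wins
  expect_equal(which.max(r$results$accuracy), 3)
  expect_error(sliding_window(ep, width = 30, start = 0, end = 100),
               "width")
})

test_that("null sliding-window accuracies show no time trend", {
  ep <- tiny_epochs(seed = 17, amp = 0, n_channels = 2, epoch_end = 160,
                    trials = 10, exemplars = default_exemplars(2))
  r <- sliding_window(ep, width = 20, start = 0, end = 160, k = 4, seed = 17,
                      control = quick_control())
  fitlm <- lm(accuracy ~ as.numeric(unit), data = r$results)
  ci <- confint(fitlm)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("unseen-exemplar evaluation reports one accuracy per exemplar", {
  ep <- tiny_epochs(seed = 18, amp = 12, trials = 8)
  r <- unseen_exemplar(extract_features(ep, c(0, 60)),
                       control = quick_control(), seed = 18)
  expect_equal(nrow(r$results), 9)           # 8 exemplars + pooled mean
  expect_setequal(r$results$unit[1:8], levels(ep$exemplar_id))
  expect_gt(pooled_acc(r), 0.8)              # category-general signal transfers
})

test_that("transfer learning returns one accuracy per dataset and rejects mismatched grids", {
  mk <- function(s) tiny_epochs(seed = s, amp = 8, n_channels = 4,
                                epoch_end = 40, trials = 8,
                                exemplars = default_exemplars(2),
                                window = c(10, 30), channels = 2:3)
  ds <- list(a = mk(31), b = mk(32), c = mk(33))
  r <- transfer_learning(ds, interval = c(0, 40), k = 4, seed = 3,
                         control = quick_control())
  expect_equal(nrow(r$results), 3)
  expect_equal(r$results$unit, c("a", "b", "c"))
  expect_true(all(r$results$accuracy > 0.5))
  bad <- mk(34); bad$data <- bad$data[, 1:3, , drop = FALSE]
  expect_error(transfer_learning(list(mk(31), bad), interval = c(0, 40)),
               "mismatched")
})

test_that("false-positive rate of the pipeline significance call is controlled", {
  sig <- vapply(1:200, function(s) {
    ep <- tiny_epochs(seed = s, amp = 0, n_channels = 2, epoch_end = 40,
                      trials = 10, exemplars = default_exemplars(2))
    r <- cross_validate(extract_features(ep, c(0, 40)), k = 4, seed = s,
                        control = quick_control())
    r$results$significant[r$results$unit == "mean"]
  }, TRUE)
  expect_lte(mean(sig), 0.075)
})
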