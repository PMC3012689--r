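test_that("band-pass keeps passband tones and suppresses out-of-band tones", {
  fs <- 500
  t <- seq(0, 2, by = 1 / fs)[-1]
  mk <- function(f) manual_epochs(array(sin(2 * pi * f * t), c(1, 1, length(t))),
                                  fs = fs)
  interior <- seq(200, length(t) - 200)
  rms <- function(x) sqrt(mean(x^2))
  out50 <- bandpass_filter(mk(50), 1, 30)
  atten_db <- 20 * log10(rms(out50$data[1, 1, interior]) /
                         rms(mk(50)$data[1, 1, interior]))
  expect_lt(atten_db, -20)
  out10 <- bandpass_filter(mk(10), 1, 30)
  expect_equal(rms(out10$data[1, 1, interior]),
               rms(mk(10)$data[1, 1, interior]), tolerance = 0.1)
  zero <- bandpass_filter(manual_epochs(array(0, c(2, 2, 300))), 1, 30)
  expect_true(all(zero$data == 0))
})

test_that("band-pass rejects cutoffs at or beyond the Nyquist frequency", {
  ep <- manual_epochs(array(rnorm(300), c(1, 1, 300)), fs = 100)
  expect_error(bandpass_filter(ep, 1, 60), "Nyquist.*50", perl = TRUE)
  expect_error(bandpass_filter(ep, 0, 30), "low")
})

test_that("epoching slices the continuous recording exactly and skips edge events", {
  fs <- 500
  data <- matrix(rnorm(2 * 3000), 2, 3000)
  rec <- structure(list(data = data, sampling_rate = fs,
                        channel_names = c("A", "B"),
                        events = data.frame(sample = c(1, 500, 1200, 2900),
                                            code = "S 1")),
                   class = "cont_recording")
  expect_warning(ep <- epoch_recording(rec, c(-300, 700)),
                 "skipped")
  expect_equal(dim(ep$data), c(2, 2, 500))   # events at 1 and 2900 dropped
  expect_equal(ep$time_ms[1], -300)
  ## direct slicing oracle
  offs <- round(seq(-300, 698, by = 2) / 2)
  expect_equal(ep$data[1, , ], data[, 500 + offs])
  expect_equal(ep$data[2, , ], data[, 1200 + offs])
})

test_that("rejection removes exactly the trials whose peak-to-peak range exceeds the threshold", {
  data <- array(rnorm(10 * 3 * 50, sd = 5), c(10, 3, 50))
  data[4, 2, ] <- seq(-120, 80, length.out = 50)   # range 200 on one channel
  ep <- manual_epochs(data)
  kept <- reject_artifacts(ep, 150)
  expect_equal(kept$n_rejected, 1)
  expect_true(kept$rejected[4])
  expect_equal(dim(kept$data)[1], 9)
  ## all-rejected is an error
  expect_error(
    reject_artifacts(manual_epochs(array(c(-100, 100, 100, -100), c(2, 1, 2))), 150),
    "all trials")
})

test_that("rejection commutes with trial permutation", {
  set.seed(5)
  data <- array(rnorm(20 * 2 * 40, sd = 30), c(20, 2, 40))
  ep <- manual_epochs(data)
  perm <- sample(20)
  r1 <- reject_artifacts(ep, 150)$rejected
  ep_p <- manual_epochs(data[perm, , , drop = FALSE])
  r2 <- reject_artifacts(ep_p, 150)$rejected
  expect_identical(r2, r1[perm])
})

test_that("rejection of symmetrically injected artifacts keeps classes near balance", {
  imb <- vapply(1:10, function(s) {
    ep <- tiny_epochs(seed = s, trials = 80)   # 640 trials, 8 exemplars
    ep <- inject_artifacts(ep, 0.05, 400, seed = s)
    kept <- reject_artifacts(ep, 150)
    abs(diff(table(kept$labels))) / length(kept$labels)
  }, 0)
  expect_lt(mean(imb), 0.015)
})

test_that("feature extraction follows the channel-major layout and round-trips", {
  ep <- tiny_epochs(seed = 2, trials = 2, exemplars = default_exemplars(2),
                    n_channels = 4, epoch_end = 60)
  fm <- extract_features(ep, c(20, 60))
  nt <- sum(ep$time_ms >= 20 & ep$time_ms < 60)
  expect_equal(ncol(fm$X), 4 * nt)
  expect_equal(fm$feature_index$channel, rep(1:4, each = nt))
  ## round-trip through feature_index reconstructs the epoch slice
  for (f in sample(ncol(fm$X), 20)) {
    fi <- fm$feature_index[f, ]
    ti <- which(ep$time_ms == fi$time_ms)
    expect_equal(fm$X[, f], ep$data[, fi$channel, ti])
  }
  expect_error(extract_features(ep, c(70, 80)), "empty interval")
})

test_that("the full-interval feature count matches sixty channels at 2-ms sampling", {
  ep <- simulate_erp(sim_config(n_trials_per_exemplar = 1, seed = 6))
  fm <- extract_features(ep, c(0, 700))
  expect_equal(ncol(fm$X), 60 * 350)
  fm40 <- extract_features(ep, c(100, 140))
  expect_equal(ncol(fm40$X), 60 * 20)
})

test_that("standardization yields exact zero mean / unit SD and stores its statistics", {
  ep <- tiny_epochs(seed = 8, trials = 6, exemplars = default_exemplars(2))
  fm <- standardize(extract_features(ep, c(0, 60)))
  expect_lt(max(abs(colMeans(fm$X))), 1e-8)
  expect_lt(max(abs(apply(fm$X, 2, sd) - 1)), 1e-8)
  ## applying the stored transform to the training set reproduces it
  raw <- extract_features(ep, c(0, 60))
  again <- apply_standardization(fm, raw)
  expect_equal(again$X, fm$X)
})

test_that("held-out trials keep training statistics (no leakage)", {
  ep <- tiny_epochs(seed = 9, trials = 16, exemplars = default_exemplars(2))
  fm <- extract_features(ep, c(0, 60))   # 64 trials
  tr <- standardize(subset_features(fm, 1:40))
  te_raw <- subset_features(fm, 41:64)
  te_train_stats <- apply_standardization(tr, te_raw)
  te_own_stats <- standardize(te_raw)
  expect_false(isTRUE(all.equal(te_train_stats$X, te_own_stats$X)))
  expect_gt(max(abs(colMeans(te_train_stats$X))), 1e-6)
})

test_that("zero-variance features are reported with their channel and time", {
  data <- array(rnorm(6 * 2 * 10), c(6, 2, 10))
  data[, 2, 3] <- 7   # constant cell: channel 2, sample 3 (4 ms)
  fm <- extract_features(manual_epochs(data), c(0, 20))
  expect_error(standardize(fm), "channel 2.*4 ms")
})

test_that("filtering and epoching commute on interior samples", {
  fs <- 500
  set.seed(12)
  x <- as.vector(stats::filter(rnorm(4000), rep(0.2, 5), sides = 2))
  x[is.na(x)] <- 0
  rec <- structure(list(data = matrix(x, 1), sampling_rate = fs,
                        channel_names = "A",
                        events = data.frame(sample = c(1000, 2500), code = "S")),
                   class = "cont_recording")
  ## a 4 Hz high-pass keeps the edge transient short enough to compare
  ## interior samples of the two orders of operations
  bf <- signal::butter(4, c(4, 30) / (fs / 2), "pass")
  rec_f <- rec
  rec_f$data[1, ] <- signal::filtfilt(bf, rec$data[1, ])
  a <- epoch_recording(rec_f, c(-300, 700))        # filter then epoch
  b <- bandpass_filter(epoch_recording(rec, c(-300, 700)), 4, 30)  # epoch then filter
  interior <- 150:350
  dev <- max(abs(a$data[, 1, interior] - b$data[, 1, interior]))
  expect_lt(dev, 0.05 * sd(a$data[, 1, interior]))
})
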