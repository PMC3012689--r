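#' Zero-phase band-pass filter of epoched data
#'
#' Applies a Butterworth band-pass forward and backward
#' (`signal::filtfilt`) per trial and channel, so the filter is zero-phase.
#'
#' @param epochs an `erp_epochs` object.
#' @param low,high band edges in Hz, `0 < low < high < Nyquist`.
#' @param order Butterworth order (default 4).
#' @return The filtered `erp_epochs` (dimensions unchanged).
#' @export
bandpass_filter <- function(epochs, low = 1, high = 30, order = 4) {
  stopifnot(inherits(epochs, "erp_epochs"))
  nyq <- epochs$sampling_rate / 2
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  if (high >= nyq)
    stop(sprintf("high cutoff %g Hz must be below the Nyquist frequency %g Hz",
                 high, nyq))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  d <- dim(epochs$data)
  for (k in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      epochs$data[k, ch, ] <- signal::filtfilt(bf, epochs$data[k, ch, ])
  epochs
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' One epoch per event; events whose window extends beyond the recording
#' are skipped with a warning. The time axis is half-open `[start, end)`
#' at the recording's sampling interval (e.g. -300, -298, ..., 698 ms for
#' a 1-s window at 500 Hz).
#'
#' @param recording a `cont_recording` (see [read_brainvision()]), i.e. a
#'   list with `data` (channels x samples), `sampling_rate`, and `events`
#'   (data.frame with column `sample`, 1-based onset sample).
#' @param window numeric length-2 window in ms relative to event onset.
#' @param labels optional per-event labels (recycled onto kept events).
#' @return An `erp_epochs` object.
#' @export
epoch_recording <- function(recording, window = c(-300, 700), labels = NULL) {
  fs <- recording$sampling_rate
  dt <- 1000 / fs
  rel <- seq(window[1], window[2] - dt / 2, by = dt)
  offs <- round(rel / dt)
  n_samp_rec <- ncol(recording$data)
  ev <- recording$events
  keep <- ev$sample + offs[1] >= 1 & ev$sample + offs[length(offs)] <= n_samp_rec
  if (any(!keep))
    warning(sprintf("%d event(s) too close to the recording edge were skipped",
                    sum(!keep)))
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events with a complete epoch window")
  n_ch <- nrow(recording$data)
  data <- array(0, dim = c(nrow(ev), n_ch, length(offs)))
  for (k in seq_len(nrow(ev)))
    data[k, , ] <- recording$data[, ev$sample[k] + offs]
  lab <- if (is.null(labels)) factor(ev$code) else factor(labels[keep])
  structure(list(data = data, time_ms = rel, labels = lab,
                 exemplar_id = factor(rep(NA_character_, nrow(ev))),
                 modality = "recorded", sampling_rate = fs,
                 ground_truth = NULL, artifact_trials = integer(0),
                 rejected = logical(nrow(ev)), config = NULL),
            class = "erp_epochs")
}

## per-trial maximum over channels of the within-epoch peak-to-peak range
trial_ranges <- function(epochs) {
  apply(epochs$data, 1, function(m) max(apply(m, 1, function(v) diff(range(v)))))
}

#' Reject trials with excessive voltage variation
#'
#' A trial is removed iff the within-epoch peak-to-peak range on any
#' channel exceeds `threshold` (the standard amplitude-based artifact
#' criterion, default 150 microvolts).
#'
#' @param epochs an `erp_epochs` object.
#' @param threshold peak-to-peak rejection threshold in microvolts (> 0).
#' @return The `erp_epochs` with offending trials removed; the
#'   `rejected` element records the decision for the *input* trials and
#'   `n_rejected` the count.
#' @export
reject_artifacts <- function(epochs, threshold = 150) {
  stopifnot(inherits(epochs, "erp_epochs"))
  if (threshold <= 0) stop("threshold must be > 0")
  rng <- trial_ranges(epochs)
  bad <- rng > threshold
  if (all(bad)) stop("all trials rejected; cannot continue")
  out <- subset_epochs(epochs, !bad)
  out$rejected <- bad
  out$n_rejected <- sum(bad)
  out
}

#' Subset trials of an epoched dataset
#'
#' @param epochs an `erp_epochs` object.
#' @param keep logical or integer trial index.
#' @return The subsetted `erp_epochs`.
#' @export
subset_epochs <- function(epochs, keep) {
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$labels <- droplevels(epochs$labels[idx])
  epochs$exemplar_id <- epochs$exemplar_id[idx]
  epochs$artifact_trials <- which(idx %in% epochs$artifact_trials)
  epochs$rejected <- logical(length(idx))
  epochs
}

#' Extract a channel x time feature matrix from epoched data
#'
#' Features are the voltage samples of all channels in the (half-open)
#' interval, ordered channel-major (all samples of channel 1, then
#' channel 2, ...). `feature_index` maps each column to its
#' (channel, time_ms) cell and is the single source of truth for feature
#' ordering.
#'
#' @param epochs an `erp_epochs` object.
#' @param interval numeric length-2 interval in ms, `[start, end)`, inside
#'   the epoch window.
#' @return An object of class `erp_features`: list with `X` (trials x
#'   features), `y` (factor labels), `feature_index` (data.frame:
#'   feature, channel, time_ms), `exemplar_id`, `n_channels`, `time_ms`,
#'   `standardized`, `center`, `scale`.
#' @export
extract_features <- function(epochs, interval = c(0, 700)) {
  stopifnot(inherits(epochs, "erp_epochs"))
  sel <- epochs$time_ms >= interval[1] & epochs$time_ms < interval[2]
  if (!any(sel)) stop("empty interval: no samples in [start, end)")
  n_trials <- dim(epochs$data)[1]
  n_ch <- dim(epochs$data)[2]
  tsel <- epochs$time_ms[sel]
  nt <- length(tsel)
  ## channel-major flatten: feature (ch-1)*nt + t
  X <- matrix(0, n_trials, n_ch * nt)
  for (ch in seq_len(n_ch))
    X[, (ch - 1) * nt + seq_len(nt)] <- epochs$data[, ch, sel]
  feature_index <- data.frame(feature = seq_len(n_ch * nt),
                              channel = rep(seq_len(n_ch), each = nt),
                              time_ms = rep(tsel, n_ch))
  structure(list(X = X, y = epochs$labels, feature_index = feature_index,
                 exemplar_id = epochs$exemplar_id, n_channels = n_ch,
                 time_ms = tsel, standardized = FALSE,
                 center = NULL, scale = NULL),
            class = "erp_features")
}

#' Standardize features to zero mean and unit standard deviation
#'
#' Per-feature z-scoring across trials. The means and SDs are stored on
#' the returned object so held-out trials can be transformed with
#' *training-set* statistics via [apply_standardization()] (the
#' leakage-safe contract).
#'
#' @param features an `erp_features` object.
#' @return The standardized `erp_features` with `center`/`scale` stored.
#' @export
standardize <- function(features) {
  stopifnot(inherits(features, "erp_features"))
  ctr <- colMeans(features$X)
  scl <- apply(features$X, 2, stats::sd)
  zero <- scl < .Machine$double.eps
  if (any(zero)) {
    i <- which(zero)[1]
    fi <- features$feature_index[i, ]
    stop(sprintf("zero-variance feature at channel %d, %g ms",
                 fi$channel, fi$time_ms))
  }
  features$X <- sweep(sweep(features$X, 2, ctr), 2, scl, "/")
  features$standardized <- TRUE
  features$center <- ctr
  features$scale <- scl
  features
}

#' Apply stored standardization statistics to new data
#'
#' @param train a standardized `erp_features` (source of center/scale).
#' @param features an `erp_features` with the same feature layout.
#' @return `features` transformed with `train`'s statistics.
#' @export
apply_standardization <- function(train, features) {
  stopifnot(inherits(train, "erp_features"), train$standardized,
            inherits(features, "erp_features"),
            ncol(features$X) == length(train$center))
  features$X <- sweep(sweep(features$X, 2, train$center), 2, train$scale, "/")
  features$standardized <- TRUE
  features$center <- train$center
  features$scale <- train$scale
  features
}

#' Subset trials of a feature matrix
#' @param features an `erp_features` object.
#' @param keep logical or integer trial index.
#' @return The subsetted `erp_features`.
#' @export
subset_features <- function(features, keep) {
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  features$X <- features$X[idx, , drop = FALSE]
  features$y <- features$y[idx]
  features$exemplar_id <- features$exemplar_id[idx]
  features
}

#' @export
print.erp_features <- function(x, ...) {
  cat(sprintf("Feature matrix: %d trials x %d features (%d channels x %d samples)%s\n",
              nrow(x$X), ncol(x$X), x$n_channels, length(x$time_ms),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}
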