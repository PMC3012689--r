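#' Specification of a spatiotemporal effect in simulated ERP data
#'
#' Describes one additive, half-sine-windowed voltage effect. With
#' `scope = "category"` the effect is added with opposite sign to the two
#' categories (+amplitude/2 vs -amplitude/2 at the half-sine peak), so the
#' difference of the class-conditional means at the peak equals `amplitude`.
#' With `scope = "exemplar"` each exemplar receives its own random channel
#' weighting (peak |weight| = 1) so the effect identifies exemplars but
#' carries no systematic category information.
#'
#' @param channels integer vector of channel indices carrying the effect.
#' @param time_window numeric length-2, effect window in ms (half-open
#'   `[start, end)`), must lie inside the epoch window.
#' @param amplitude peak amplitude in microvolts (>= 0).
#' @param polarity +1 or -1.
#' @param scope `"category"` (category-general) or `"exemplar"`
#'   (exemplar-specific).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(channels, time_window, amplitude, polarity = 1,
                        scope = c("category", "exemplar")) {
  scope <- match.arg(scope)
  stopifnot(length(time_window) == 2, time_window[1] < time_window[2])
  if (amplitude < 0) stop("effect amplitude must be >= 0")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  structure(list(channels = as.integer(channels),
                 time_window = as.numeric(time_window),
                 amplitude = as.numeric(amplitude),
                 polarity = polarity, scope = scope),
            class = "effect_spec")
}

#' Noise specification for simulated ERP data
#'
#' Background noise is spatially mixed white noise passed through a
#' per-channel AR(1) recursion, rescaled so that the marginal per-channel
#' standard deviation equals `background_sd`.
#'
#' @param background_sd marginal noise SD per channel, microvolts (> 0).
#' @param ar_coefficient AR(1) coefficient in (-1, 1); controls temporal
#'   autocorrelation at the sampling interval.
#' @param spatial_neighbors number of neighboring channels (each side, by
#'   channel index) averaged into each channel to induce inter-channel
#'   correlation.
#' @param erp_background_amplitude amplitude (microvolts) of the shared,
#'   class-independent ERP background waves.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(background_sd = 8, ar_coefficient = 0.9,
                       spatial_neighbors = 2, erp_background_amplitude = 5) {
  if (background_sd <= 0) stop("background_sd must be > 0")
  if (abs(ar_coefficient) >= 1) stop("|ar_coefficient| must be < 1")
  structure(list(background_sd = background_sd,
                 ar_coefficient = ar_coefficient,
                 spatial_neighbors = as.integer(spatial_neighbors),
                 erp_background_amplitude = erp_background_amplitude),
            class = "noise_spec")
}

#' Default exemplar set: two categories x four exemplars
#'
#' @param n_per_category exemplars per category.
#' @return data.frame with columns `exemplar` and `category`.
#' @export
default_exemplars <- function(n_per_category = 4) {
  data.frame(
    exemplar = c(paste0("animal", seq_len(n_per_category)),
                 paste0("tool", seq_len(n_per_category))),
    category = rep(c("animal", "tool"), each = n_per_category),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic ERP generator
#'
#' Defaults emulate a typical single-subject ERP session: 60 channels
#' sampled at 500 Hz, 1-s epochs from -300 to +700 ms around stimulus
#' onset, and 8 exemplars (2 categories x 4 exemplars) repeated 80 times
#' each, i.e. 640 trials.
#'
#' @param n_channels number of EEG channels.
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_window numeric length-2 epoch window in ms relative to
#'   stimulus onset (half-open `[start, end)`).
#' @param n_trials_per_exemplar repetitions of each exemplar.
#' @param exemplars data.frame with columns `exemplar`, `category`.
#' @param category_effect,exemplar_effect lists of [effect_spec()] objects
#'   (scope is forced to match the argument).
#' @param noise a [noise_spec()].
#' @param artifact_rate fraction of trials receiving a high-amplitude
#'   artifact, in `[0, 1]`.
#' @param artifact_amplitude artifact peak amplitude in microvolts.
#' @param seed master seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 60, sampling_rate = 500,
                       epoch_window = c(-300, 700),
                       n_trials_per_exemplar = 80,
                       exemplars = default_exemplars(),
                       category_effect = list(), exemplar_effect = list(),
                       noise = noise_spec(),
                       artifact_rate = 0, artifact_amplitude = 200,
                       seed = 1) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (epoch_window[1] >= epoch_window[2]) stop("epoch window start must precede end")
  if (artifact_rate < 0 || artifact_rate > 1) stop("artifact_rate must lie in [0, 1]")
  stopifnot(is.data.frame(exemplars),
            all(c("exemplar", "category") %in% names(exemplars)))
  if (length(unique(exemplars$category)) != 2)
    stop("exactly two categories are required")
  if (inherits(category_effect, "effect_spec")) category_effect <- list(category_effect)
  if (inherits(exemplar_effect, "effect_spec")) exemplar_effect <- list(exemplar_effect)
  all_eff <- c(category_effect, exemplar_effect)
  for (ef in all_eff) {
    if (ef$time_window[1] < epoch_window[1] || ef$time_window[2] > epoch_window[2])
      stop(sprintf("effect window [%g, %g) lies outside the epoch window [%g, %g)",
                   ef$time_window[1], ef$time_window[2],
                   epoch_window[1], epoch_window[2]))
    if (any(ef$channels < 1 | ef$channels > n_channels))
      stop("effect channels outside 1..n_channels")
  }
  structure(list(n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate,
                 epoch_window = as.numeric(epoch_window),
                 n_trials_per_exemplar = as.integer(n_trials_per_exemplar),
                 exemplars = exemplars,
                 category_effect = category_effect,
                 exemplar_effect = exemplar_effect,
                 noise = noise,
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## half-sine bump over a half-open time window [t0, t1), zero elsewhere
half_sine <- function(time_ms, t0, t1) {
  w <- numeric(length(time_ms))
  inside <- time_ms >= t0 & time_ms < t1
  w[inside] <- sin(pi * (time_ms[inside] - t0) / (t1 - t0))
  w
}

## deterministic per-trial substream seed from a master seed
trial_seed <- function(master, k) {
  as.integer((as.double(master) * 10007 + k * 127 + 1) %% 2147483629)
}

## class-independent ERP background: three smooth half-sine waves with
## channel-profile gains (P1-like, N1-like, late positivity)
erp_background <- function(n_channels, time_ms, amplitude) {
  comps <- list(list(t0 = 80, t1 = 150, pol = +1, ph = 0.0),
                list(t0 = 130, t1 = 230, pol = -1, ph = 1.5),
                list(t0 = 250, t1 = 600, pol = +0.6, ph = 3.0))
  bg <- matrix(0, n_channels, length(time_ms))
  ch <- seq_len(n_channels)
  for (cp in comps) {
    gain <- 0.5 + 0.5 * sin(2 * pi * ch / n_channels + cp$ph)
    bg <- bg + amplitude * cp$pol * (gain %o% half_sine(time_ms, cp$t0, cp$t1))
  }
  bg
}

#' Generate a synthetic epoched ERP dataset
#'
#' Each trial is the sum of a shared ERP background, the configured
#' category-general and exemplar-specific effects, and spatially mixed
#' AR(1) noise. The returned object carries a ground-truth mask marking
#' exactly the channel x time cells of the category-general effects.
#' Per-trial noise streams are derived deterministically from the master
#' seed, so the same config yields bit-identical data.
#'
#' @param config a [sim_config()].
#' @return An object of class `erp_epochs`: a list with elements `data`
#'   (trials x channels x samples array, microvolts), `time_ms`, `labels`
#'   (factor, category per trial), `exemplar_id`, `modality`,
#'   `sampling_rate`, `ground_truth` (channels x samples logical mask),
#'   and `artifact_trials`.
#' @export
simulate_erp <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  dt <- 1000 / fs
  time_ms <- seq(config$epoch_window[1], config$epoch_window[2] - dt / 2, by = dt)
  n_samp <- length(time_ms)
  n_ch <- config$n_channels
  ex <- config$exemplars
  n_ex <- nrow(ex)
  n_trials <- config$n_trials_per_exemplar * n_ex
  cats <- sort(unique(ex$category))

  exemplar_id <- rep(ex$exemplar, each = config$n_trials_per_exemplar)
  labels <- rep(ex$category, each = config$n_trials_per_exemplar)

  ## shared background
  bg <- erp_background(n_ch, time_ms, config$noise$erp_background_amplitude)

  ## category effect template (added +/- half to the two categories)
  cat_eff <- matrix(0, n_ch, n_samp)
  mask <- matrix(FALSE, n_ch, n_samp)
  for (ef in config$category_effect) {
    if (ef$scope != "category") next
    w <- half_sine(time_ms, ef$time_window[1], ef$time_window[2])
    cat_eff[ef$channels, ] <- cat_eff[ef$channels, , drop = FALSE] +
      ef$polarity * ef$amplitude *
      matrix(w, length(ef$channels), n_samp, byrow = TRUE)
    mask[ef$channels, w > 0] <- TRUE
  }

  ## exemplar-specific effect templates: the effect window is divided
  ## into one sub-window per exemplar, and each exemplar receives a
  ## half-sine deflection with random channel weights in its own
  ## sub-window only. Signatures of different exemplars are therefore
  ## orthogonal in the channel x time grid and carry no systematic
  ## category structure (exemplar identity, not category, is encoded).
  ex_eff <- vector("list", n_ex)
  set.seed(trial_seed(config$seed, -1))
  for (e in seq_len(n_ex)) {
    tmpl <- matrix(0, n_ch, n_samp)
    for (ef in config$exemplar_effect) {
      if (ef$scope != "exemplar") next
      edges <- seq(ef$time_window[1], ef$time_window[2], length.out = n_ex + 1)
      wch <- stats::rnorm(length(ef$channels))
      wch <- wch / max(abs(wch))
      w <- half_sine(time_ms, edges[e], edges[e + 1])
      tmpl[ef$channels, ] <- tmpl[ef$channels, , drop = FALSE] +
        ef$polarity * ef$amplitude * (wch %o% w)
    }
    ex_eff[[e]] <- tmpl
  }

  ## noise innovations per trial (deterministic substreams), then spatial
  ## mixing and AR(1) recursion applied jointly
  noise <- array(0, dim = c(n_ch, n_samp, n_trials))
  for (k in seq_len(n_trials)) {
    set.seed(trial_seed(config$seed, k))
    noise[, , k] <- stats::rnorm(n_ch * n_samp)
  }
  ns <- config$noise$spatial_neighbors
  if (ns > 0) {
    S <- matrix(0, n_ch, n_ch)
    for (i in seq_len(n_ch)) {
      idx <- max(1, i - ns):min(n_ch, i + ns)
      S[i, idx] <- 1 / length(idx)
    }
    dim(noise) <- c(n_ch, n_samp * n_trials)
    noise <- S %*% noise
    dim(noise) <- c(n_ch, n_samp, n_trials)
    row_var <- rowSums(S^2)
  } else {
    row_var <- rep(1, n_ch)
  }
  phi <- config$noise$ar_coefficient
  noise[, 1, ] <- noise[, 1, ] / sqrt(1 - phi^2)   # stationary start
  for (t in 2:n_samp) noise[, t, ] <- phi * noise[, t - 1, ] + noise[, t, ]
  scale_ch <- config$noise$background_sd / sqrt(row_var / (1 - phi^2))
  noise <- noise * scale_ch   # recycles over channels (first dimension)

  ## assemble trials x channels x samples
  data <- array(0, dim = c(n_trials, n_ch, n_samp))
  cat_sign <- ifelse(labels == cats[2], +0.5, -0.5)
  ex_index <- match(exemplar_id, ex$exemplar)
  for (k in seq_len(n_trials)) {
    data[k, , ] <- bg + cat_sign[k] * cat_eff + ex_eff[[ex_index[k]]] + noise[, , k]
  }

  out <- structure(list(
    data = data,
    time_ms = time_ms,
    labels = factor(labels, levels = cats),
    exemplar_id = factor(exemplar_id, levels = ex$exemplar),
    modality = "synthetic",
    sampling_rate = fs,
    ground_truth = mask,
    artifact_trials = integer(0),
    rejected = logical(n_trials),
    config = config), class = "erp_epochs")
  if (config$artifact_rate > 0)
    out <- inject_artifacts(out, config$artifact_rate,
                            config$artifact_amplitude,
                            seed = trial_seed(config$seed, -2))
  out
}

#' Inject high-amplitude transient artifacts into selected trials
#'
#' `floor(rate * n_trials)` randomly chosen trials receive a half-sine
#' transient of the given peak amplitude on one random channel; affected
#' trials are recorded in `artifact_trials`.
#'
#' @param epochs an `erp_epochs` object.
#' @param rate fraction of trials to contaminate, in `[0, 1]`.
#' @param amplitude artifact peak amplitude in microvolts (> 0).
#' @param seed RNG seed for trial/channel selection.
#' @return The modified `erp_epochs` object.
#' @export
inject_artifacts <- function(epochs, rate, amplitude, seed = 1) {
  stopifnot(inherits(epochs, "erp_epochs"))
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (amplitude <= 0) stop("amplitude must be > 0")
  n_trials <- dim(epochs$data)[1]
  n_ch <- dim(epochs$data)[2]
  n_art <- floor(rate * n_trials)
  if (n_art == 0) return(epochs)
  set.seed(seed)
  picked <- sort(sample.int(n_trials, n_art))
  t_ms <- epochs$time_ms
  span <- diff(range(t_ms))
  for (k in picked) {
    ch <- sample.int(n_ch, 1)
    t0 <- t_ms[1] + stats::runif(1, 0.1, 0.7) * span
    w <- half_sine(t_ms, t0, t0 + 0.2 * span)
    epochs$data[k, ch, ] <- epochs$data[k, ch, ] + amplitude * w
  }
  epochs$artifact_trials <- sort(union(epochs$artifact_trials, picked))
  epochs
}

#' @export
print.erp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoched ERP dataset: %d trials x %d channels x %d samples\n",
              d[1], d[2], d[3]))
  cat(sprintf("  time: %g..%g ms @ %g Hz; modality: %s\n",
              min(x$time_ms), max(x$time_ms), x$sampling_rate, x$modality))
  print(table(category = x$labels))
  if (length(x$artifact_trials))
    cat(sprintf("  %d trials flagged with injected artifacts\n",
                length(x$artifact_trials)))
  invisible(x)
}
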