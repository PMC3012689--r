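# Shared fixtures and small utilities for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# closed-form standard Laplace CDF
plaplace <- function(q) ifelse(q < 0, 0.5 * exp(q), 1 - 0.5 * exp(-q))

# 99% two-sided binomial band around 0.5
chance_band <- function(n) 2.576 * sqrt(0.25 / n)

# small epoched dataset, optionally with a category effect
tiny_epochs <- function(seed = 1, amp = 0, n_channels = 6, epoch_end = 60,
                        trials = 10, exemplars = default_exemplars(),
                        noise = noise_spec(), window = c(20, 50),
                        channels = 2:4) {
  eff <- if (amp > 0) list(effect_spec(channels, window, amp)) else list()
  simulate_erp(sim_config(n_channels = n_channels,
                          epoch_window = c(0, epoch_end),
                          n_trials_per_exemplar = trials,
                          exemplars = exemplars,
                          category_effect = eff, noise = noise, seed = seed))
}

# epochs object wrapping an explicit trials x channels x samples array
manual_epochs <- function(data, fs = 500, t0 = 0, labels = NULL) {
  n <- dim(data)[1]
  if (is.null(labels)) labels <- factor(rep(c("a", "b"), length.out = n))
  structure(list(data = data,
                 time_ms = seq(t0, by = 1000 / fs, length.out = dim(data)[3]),
                 labels = labels,
                 exemplar_id = factor(rep("x", n)),
                 modality = "manual", sampling_rate = fs,
                 ground_truth = NULL, artifact_trials = integer(0),
                 rejected = logical(n), config = NULL),
            class = "erp_epochs")
}

# fast EP control for small fits
quick_control <- function() mvlaplace_control(max_iter = 80)

# pooled CV accuracy from a report
pooled_acc <- function(report) {
  report$results$accuracy[report$results$unit == "mean"]
}

# write a minimal BrainVision triplet; returns the header path
write_bv_fixture <- function(dir, n_ch = 3, n_samp = 200, fs = 500,
                             format = "INT_16", resolution = 0.1,
                             markers = c(50, 100, 150)) {
  vhdr <- file.path(dir, "rec.vhdr")
  vmrk <- file.path(dir, "rec.vmrk")
  eeg <- file.path(dir, "rec.eeg")
  set.seed(99)
  data <- matrix(rnorm(n_ch * n_samp, sd = 20), n_ch, n_samp)
  if (format == "INT_16") {
    ints <- round(data / resolution)
    writeBin(as.integer(as.vector(ints)), eeg, size = 2, endian = "little")
    stored <- matrix(as.numeric(as.integer(ints)), n_ch) * resolution
  } else {
    writeBin(as.vector(data), eeg, size = 4, endian = "little")
    stored <- matrix(readBin(eeg, "numeric", n_ch * n_samp, size = 4,
                             endian = "little"), n_ch)
  }
  ch_lines <- sprintf("Ch%d=EEG%02d,,%g,µV", seq_len(n_ch), seq_len(n_ch),
                      resolution)
  writeLines(c("Brain Vision Data Exchange Header File Version 1.0",
               "[Common Infos]",
               "DataFile=rec.eeg", "MarkerFile=rec.vmrk",
               "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
               sprintf("NumberOfChannels=%d", n_ch),
               sprintf("SamplingInterval=%g", 1e6 / fs),
               "[Binary Infos]",
               sprintf("BinaryFormat=%s", format),
               "[Channel Infos]", ch_lines), vhdr)
  mk_lines <- sprintf("Mk%d=Stimulus,S %d,%d,1,0", seq_along(markers),
                      seq_along(markers), markers)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]", "Codepage=UTF-8", "DataFile=rec.eeg",
               "[Marker Infos]",
               "Mk0=New Segment,,1,1,0", mk_lines), vmrk)
  list(vhdr = vhdr, data = stored, markers = markers)
}
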