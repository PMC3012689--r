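CONTAINER_SCHEMA <- "erpdecode-container"
CONTAINER_VERSION <- 1L

#' Write an object to the internal single-file container
#'
#' Stores epoched data, feature matrices, fits, or evaluation reports in
#' a versioned single-file container (R serialization with an explicit
#' schema envelope), losslessly.
#'
#' @param object one of `erp_epochs`, `erp_features`, `mvlaplace`,
#'   `erp_eval`, `importance_map`.
#' @param path output path.
#' @param provenance optional named list (seeds, parameters, hashes)
#'   stored alongside the payload.
#' @export
write_container <- function(object, path, provenance = list()) {
  cls <- class(object)[1]
  if (!cls %in% c("erp_epochs", "erp_features", "mvlaplace", "erp_eval",
                  "importance_map", "cont_recording"))
    stop(sprintf("unsupported object class '%s'", cls))
  validate_payload(object, cls)
  env <- list(schema = CONTAINER_SCHEMA, version = CONTAINER_VERSION,
              class = cls, payload = object,
              provenance = c(provenance,
                             list(package_version = as.character(utils::packageVersion("erpdecode")),
                                  written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))))
  saveRDS(env, path)
  invisible(path)
}

#' Read an object back from the internal container
#' @param path container path.
#' @return The stored object with attribute `"provenance"`.
#' @export
read_container <- function(path) {
  env <- readRDS(path)
  if (!is.list(env) || !identical(env$schema, CONTAINER_SCHEMA))
    stop("not an erpdecode container")
  if (!identical(env$version, CONTAINER_VERSION))
    stop(sprintf("container schema version %s does not match supported version %d",
                 env$version, CONTAINER_VERSION))
  validate_payload(env$payload, env$class)
  obj <- env$payload
  attr(obj, "provenance") <- env$provenance
  obj
}

validate_payload <- function(object, cls) {
  if (cls == "erp_epochs") {
    if (is.null(object$data) || is.null(object$labels))
      stop("container validation: epoched dataset is missing data or labels")
    if (dim(object$data)[1] != length(object$labels))
      stop("container validation: label count does not match trial count")
  }
  if (cls == "erp_features" && (is.null(object$X) || is.null(object$y)))
    stop("container validation: feature matrix is missing X or labels")
  invisible(TRUE)
}

## ---------------------------------------------------------------------
## BrainVision reader (common dialect: INT_16 / IEEE_FLOAT_32, multiplexed)

parse_vhdr_section <- function(lines, section) {
  hdr <- grep(sprintf("^\\[%s\\]", section), lines)
  if (!length(hdr)) return(character(0))
  rest <- lines[(hdr[1] + 1):length(lines)]
  nxt <- grep("^\\[", rest)
  if (length(nxt)) rest <- rest[seq_len(nxt[1] - 1)]
  rest[grepl("=", rest) & !grepl("^;", rest)]
}

kv <- function(entries) {
  keys <- sub("=.*$", "", entries)
  vals <- sub("^[^=]*=", "", entries)
  stats::setNames(trimws(vals), trimws(keys))
}

#' Read a BrainVision recording (.vhdr / .vmrk / .eeg triplet)
#'
#' Supports the common dialect: binary data, `MULTIPLEXED` orientation,
#' `INT_16` (with per-channel resolution scaling) or `IEEE_FLOAT_32`
#' formats. Anything else is rejected with an error naming the offending
#' header field. Stimulus markers become events.
#'
#' @param header_path path to the `.vhdr` text header.
#' @return An object of class `cont_recording`: list with `data`
#'   (channels x samples matrix, microvolts), `sampling_rate` (Hz),
#'   `channel_names`, and `events` (data.frame: `sample`, `code`).
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  lines <- readLines(header_path, warn = FALSE)
  common <- kv(parse_vhdr_section(lines, "Common Infos"))
  if (!"DataFile" %in% names(common))
    stop("corrupt header: no DataFile entry in [Common Infos]")
  get_common <- function(key) if (key %in% names(common)) common[[key]] else NULL
  dir <- dirname(header_path)
  data_file <- file.path(dir, common[["DataFile"]])
  if (!file.exists(data_file)) stop("referenced DataFile not found: ", data_file)
  fmt <- get_common("DataFormat")
  if (!is.null(fmt) && toupper(fmt) != "BINARY")
    stop("unsupported DataFormat '", fmt, "' (only BINARY is supported)")
  orient <- get_common("DataOrientation")
  if (!is.null(orient) && toupper(orient) != "MULTIPLEXED")
    stop("unsupported DataOrientation '", orient, "' (only MULTIPLEXED is supported)")
  if (!all(c("NumberOfChannels", "SamplingInterval") %in% names(common)))
    stop("corrupt header: missing NumberOfChannels or SamplingInterval")
  n_ch <- as.integer(common[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(common[["SamplingInterval"]])  # header stores microseconds

  binfmt <- kv(parse_vhdr_section(lines, "Binary Infos"))[["BinaryFormat"]]
  if (is.null(binfmt)) binfmt <- "INT_16"
  binfmt <- toupper(binfmt)
  if (!binfmt %in% c("INT_16", "IEEE_FLOAT_32"))
    stop("unsupported BinaryFormat '", binfmt,
         "' (only INT_16 and IEEE_FLOAT_32 are supported)")

  ch_entries <- kv(parse_vhdr_section(lines, "Channel Infos"))
  ch_parts <- strsplit(unname(ch_entries), ",")
  ch_names <- vapply(ch_parts, `[`, "", 1)
  resolution <- vapply(ch_parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)

  sz <- file.size(data_file)
  if (binfmt == "INT_16") {
    n_total <- sz / 2
    raw <- readBin(data_file, "integer", n = n_total, size = 2, signed = TRUE,
                   endian = "little")
    data <- matrix(as.numeric(raw), nrow = n_ch) * resolution
  } else {
    n_total <- sz / 4
    raw <- readBin(data_file, "numeric", n = n_total, size = 4,
                   endian = "little")
    data <- matrix(raw, nrow = n_ch) * resolution
  }

  events <- data.frame(sample = integer(0), code = character(0))
  if (!is.null(get_common("MarkerFile")) && nzchar(common[["MarkerFile"]])) {
    marker_file <- file.path(dir, common[["MarkerFile"]])
    if (!file.exists(marker_file))
      stop("referenced MarkerFile not found: ", marker_file)
    mk <- kv(parse_vhdr_section(readLines(marker_file, warn = FALSE),
                                "Marker Infos"))
    parts <- strsplit(unname(mk), ",")
    type <- vapply(parts, `[`, "", 1)
    desc <- vapply(parts, `[`, "", 2)
    pos <- as.integer(vapply(parts, `[`, "", 3))
    stim <- type == "Stimulus"
    events <- data.frame(sample = pos[stim], code = desc[stim],
                         stringsAsFactors = FALSE)
  }
  if (nrow(events) && any(events$sample < 1 | events$sample > ncol(data)))
    stop("marker positions outside the recording length")
  structure(list(data = data, sampling_rate = fs, channel_names = ch_names,
                 events = events), class = "cont_recording")
}

#' @export
print.cont_recording <- function(x, ...) {
  cat(sprintf("Continuous recording: %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, nrow(x$events)))
  invisible(x)
}

## ---------------------------------------------------------------------
## Run configuration: plain key=value file, unknown keys rejected

run_config_defaults <- function() {
  list(n_channels = 60, sampling_rate = 500, epoch_start = -300,
       epoch_end = 700, n_trials_per_exemplar = 80,
       filter_low = 1, filter_high = 30, filter_order = 4,
       reject_threshold = 150, interval_start = 0, interval_end = 700,
       window_width = 40, window_start = 0, window_end = 640,
       k = 5, coupling = 100, lambda = 1, seed = 1,
       preset = "null", effect_amplitude = 0)
}

#' Create a run configuration
#'
#' Bundles the stage parameters of the whole pipeline with a provenance
#' block (config hash, package version). Unknown keys are rejected.
#'
#' @param ... overrides of the default keys (see
#'   `erpdecode:::run_config_defaults()`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

config_text <- function(cfg) {
  paste0(names(cfg), " = ", vapply(cfg, as.character, ""), collapse = "\n")
}

#' Write a run configuration as a plain key=value file
#' @param cfg a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  writeLines(c("# erpdecode run configuration", config_text(cfg)), path)
  invisible(path)
}

#' Read a run configuration from a key=value file
#' @param path config file path.
#' @return A [run_config()]; unknown keys raise an error.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines) & !grepl("^\\s*#", lines)]
  pairs <- kv(lines)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(pairs), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  vals <- lapply(names(pairs), function(k) {
    v <- pairs[[k]]
    if (is.numeric(defaults[[k]])) as.numeric(v) else v
  })
  do.call(run_config, stats::setNames(vals, names(pairs)))
}

#' Provenance block for a configuration
#' @param cfg a [run_config()].
#' @return list with `config_hash` (MD5 of the canonical key=value text),
#'   `package_version`, and `timestamp`.
#' @export
config_provenance <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(config_text(cfg), tf)
  list(config_hash = unname(tools::md5sum(tf)),
       package_version = as.character(utils::packageVersion("erpdecode")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' @export
print.run_config <- function(x, ...) {
  cat("erpdecode run configuration\n")
  cat(config_text(x), "\n")
  invisible(x)
}
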