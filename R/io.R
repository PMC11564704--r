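#' Epoch collection container
#'
#' The unit data structure of the pipeline: a 3-d array of fixed-length
#' epochs (epoch x channel x sample) with the sampling rate, channel names,
#' one class label per epoch and provenance metadata.
#'
#' @param epochs numeric array `n_epochs x n_channels x epoch_length`.
#' @param sampling_rate Hz.
#' @param channel_names character vector, one per channel.
#' @param labels per-epoch class labels.
#' @param provenance free-form list (file, seed, ...).
#' @return A list of class `epoch_collection`.
#' @export
epoch_collection <- function(epochs, sampling_rate, channel_names = NULL,
                             labels = NULL, provenance = list()) {
  d <- dim(epochs)
  if (length(d) != 3L) stop("epochs must be a 3-d array")
  if (d[2L] < 1L) stop("need at least one channel")
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(d[2L]))
  if (length(channel_names) != d[2L]) stop("one name per channel required")
  if (!is.null(labels) && length(labels) != d[1L])
    stop("labels must align with epochs")
  structure(list(epochs = epochs, sampling_rate = sampling_rate,
                 channel_names = channel_names,
                 labels = if (is.null(labels)) NULL else as.factor(labels),
                 provenance = provenance),
            class = "epoch_collection")
}

#' @export
print.epoch_collection <- function(x, ...) {
  d <- dim(x$epochs)
  cat("Epoch collection: ", d[1L], " epochs x ", d[2L], " channels x ",
      d[3L], " samples @ ", x$sampling_rate, " Hz\n", sep = "")
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

segment_epochs <- function(signals, epoch_length) {
  # signals: channels x samples matrix -> epochs x channels x epoch_length
  n <- ncol(signals)
  n_ep <- n %/% epoch_length
  dropped <- n - n_ep * epoch_length
  if (dropped > 0L)
    message("dropping trailing remainder of ", dropped, " samples")
  arr <- array(0, dim = c(n_ep, nrow(signals), epoch_length))
  for (e in seq_len(n_ep))
    arr[e, , ] <- signals[, ((e - 1L) * epoch_length + 1L):(e * epoch_length)]
  arr
}

resolve_labels <- function(labels, labels_path, n_epochs) {
  if (!is.null(labels_path)) {
    df <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    if ("epoch_id" %in% names(df)) {
      labels <- df$label[order(df$epoch_id)]
    } else {
      labels <- df$label[1L] # recording-level label
    }
  }
  if (is.null(labels)) stop("missing labels: supply labels= or labels_path=")
  if (length(labels) == 1L) labels <- rep(labels, n_epochs)
  if (length(labels) != n_epochs)
    stop("got ", length(labels), " labels for ", n_epochs, " epochs")
  labels
}

#' Read a multichannel recording and segment it into epochs
#'
#' Supports two sources: a delimited numeric matrix (comma-separated, one
#' row per channel, optionally a leading column of channel names) and
#' continuous 16-bit EDF (European Data Format). The recording is cut into
#' consecutive non-overlapping epochs of `epoch_length` samples; a trailing
#' remainder is dropped with a message. Labels may be per-epoch or a single
#' recording-level class applied to every epoch, given directly or as a CSV
#' (`epoch_id,label` rows, or a single `label` for the recording).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param epoch_length samples per epoch (default 3750, 15 s at 250 Hz).
#' @param sampling_rate Hz; required for CSV, read from the header for EDF
#'   (supplying a conflicting value is an error).
#' @param labels label vector (length 1 or one per epoch), or `NULL`.
#' @param labels_path CSV of labels, alternative to `labels`.
#' @return An [epoch_collection()]. A recording shorter than one epoch
#'   yields an empty collection with a warning.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           epoch_length = 3750L, sampling_rate = NULL,
                           labels = NULL, labels_path = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") {
    df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
    first_numeric <- suppressWarnings(!any(is.na(as.numeric(df[[1L]]))))
    if (first_numeric) {
      channel_names <- sprintf("ch%02d", seq_len(nrow(df)))
      signals <- as.matrix(df)
    } else {
      channel_names <- as.character(df[[1L]])
      signals <- as.matrix(df[, -1L, drop = FALSE])
    }
    storage.mode(signals) <- "double"
    if (is.null(sampling_rate))
      stop("sampling_rate is required for delimited input")
    fs <- sampling_rate
  } else {
    edf <- read_edf(path)
    signals <- edf$signals
    channel_names <- edf$channel_names
    fs <- edf$sampling_rate
    if (!is.null(sampling_rate) && sampling_rate != fs)
      stop("sampling-rate mismatch: file says ", fs, " Hz, config says ",
           sampling_rate)
  }
  if (ncol(signals) < epoch_length) {
    warning("recording shorter than one epoch; returning an empty collection")
    return(epoch_collection(array(0, c(0L, nrow(signals), epoch_length)),
                            sampling_rate = fs, channel_names = channel_names,
                            labels = NULL,
                            provenance = list(file = path)))
  }
  arr <- segment_epochs(signals, epoch_length)
  labels <- resolve_labels(labels, labels_path, dim(arr)[1L])
  epoch_collection(arr, sampling_rate = fs, channel_names = channel_names,
                   labels = labels, provenance = list(file = path))
}

pad_ascii <- function(x, width) {
  x <- as.character(x)
  formatC(substr(x, 1L, width), width = -width)
}

#' Minimal continuous EDF reader / writer
#'
#' Reads (and, mainly for testing, writes) continuous 16-bit EDF files:
#' ASCII header, per-signal subheaders, little-endian 16-bit data records
#' with linear physical scaling. All signals must share one sampling rate.
#' Annotations, discontinuous files and EDF+ extensions are out of scope.
#'
#' @param path file path.
#' @return `read_edf`: a list with `signals` (channels x samples matrix),
#'   `channel_names`, `sampling_rate`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8L + 80L + 80L + 8L + 8L) # version, patient, recording, date, time
  rd(8L)                       # header bytes
  rd(44L)                      # reserved
  n_rec <- as.integer(rd(8L))
  dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  fields <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fields(16L)
  fields(80L); fields(8L)      # transducer, physical dimension
  pmin <- as.numeric(fields(8L)); pmax <- as.numeric(fields(8L))
  dmin <- as.numeric(fields(8L)); dmax <- as.numeric(fields(8L))
  fields(80L)                  # prefiltering
  spr <- as.integer(fields(8L))
  fields(32L)                  # reserved
  if (length(unique(spr / dur)) != 1L)
    stop("signals with differing sampling rates are not supported")
  sig <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L,
                     signed = TRUE, endian = "little")
      phys <- pmin[s] + (dig - dmin[s]) * (pmax[s] - pmin[s]) / (dmax[s] - dmin[s])
      sig[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
  }
  list(signals = sig, channel_names = labels,
       sampling_rate = spr[1L] / dur)
}

#' @rdname read_edf
#' @param signals channels x samples numeric matrix; sample count must be a
#'   multiple of `sampling_rate` (1-second records).
#' @param sampling_rate Hz.
#' @param channel_names one per channel.
#' @param physical_range `c(min, max)` mapped onto the full 16-bit digital
#'   range; the default equals the digital range so integer-valued signals
#'   round-trip exactly.
#' @export
write_edf <- function(path, signals, sampling_rate,
                      channel_names = NULL,
                      physical_range = c(-32768, 32767)) {
  ns <- nrow(signals)
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(ns))
  spr <- as.integer(sampling_rate)
  if (ncol(signals) %% spr != 0L)
    stop("sample count must be a multiple of the sampling rate")
  n_rec <- ncol(signals) %/% spr
  dmin <- -32768; dmax <- 32767
  phys_lo <- physical_range[1L]; phys_hi <- physical_range[2L]
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad_ascii(x, w), con, eos = NULL)
  wr("0", 8L); wr("synthetic", 80L); wr("synthetic", 80L)
  wr("01.01.24", 8L); wr("00.00.00", 8L)
  wr(256L + ns * 256L, 8L); wr("", 44L)
  wr(n_rec, 8L); wr(1, 8L); wr(ns, 4L)
  for (nm in channel_names) wr(nm, 16L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(ns)) wr("uV", 8L)
  for (i in seq_len(ns)) wr(phys_lo, 8L)
  for (i in seq_len(ns)) wr(phys_hi, 8L)
  for (i in seq_len(ns)) wr(dmin, 8L)
  for (i in seq_len(ns)) wr(dmax, 8L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(ns)) wr(spr, 8L)
  for (i in seq_len(ns)) wr("", 32L)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      phys <- signals[s, ((r - 1L) * spr + 1L):(r * spr)]
      dig <- round((phys - phys_lo) / (phys_hi - phys_lo) * (dmax - dmin) + dmin)
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

pipeline_defaults <- function() {
  list(epoch_length = 3750L, sampling_rate = 250, iv = 100L, fv = 512L,
       k = 1L, folds = 10L, wavelet = "db4", levels = 4L,
       boundary = "symmetric", ihmv_r_min = 3L)
}

#' Load a pipeline configuration
#'
#' Reads an optional YAML config and fills any missing keys with the
#' pipeline defaults (epoch length 3750 at 250 Hz; selection sweep 100-512;
#' 1NN with 10-fold CV; db4, 4 levels). Filled keys are recorded in the
#' `filled` attribute.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list overriding both file values and defaults.
#' @return Configuration list with attribute `filled`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  defaults <- pipeline_defaults()
  filled <- setdiff(names(defaults), names(cfg))
  cfg[filled] <- defaults[filled]
  if (length(filled))
    message("using defaults for: ", paste(filled, collapse = ", "))
  structure(cfg, filled = filled)
}

#' Run manifest
#'
#' Builds (and optionally writes) a manifest describing a pipeline run:
#' the configuration and its hash, seed, package and R versions, and
#' per-stage timings. The hash covers only configuration and seed, so two
#' runs of the same setup hash identically regardless of timing.
#'
#' @param config configuration list (see [load_config()]).
#' @param results a `lattice_run`, or `NULL`.
#' @param path optional JSON output path.
#' @param seed the run seed recorded (defaults to `config$seed` when set).
#' @return The manifest list, invisibly if written.
#' @export
log_run <- function(config, results = NULL, path = NULL, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  key <- config[order(names(config))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(list(config = key, seed = seed), tmp,
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config = config,
    seed = seed,
    hash = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("lattice123")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    timings = if (!is.null(results)) list(total_s = results$elapsed))
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(manifest))
  }
  manifest
}
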