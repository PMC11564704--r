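feature_sources <- c("raw", "L1", "L2", "L3", "L4")

#' Multilevel channel features
#'
#' Applies the lattice graph pattern transform to the raw signal and to its
#' four low-pass wavelet subbands, and concatenates the resulting 256-bin
#' histograms source-wise: for each of the six categories the feature vector
#' is `[raw | L1 | L2 | L3 | L4]`, length 1280. Each source signal is
#' normalized and thresholded independently.
#'
#' @param signal one epoch of one channel (numeric vector; long enough for a
#'   `levels`-level decomposition whose last subband holds >= 19 samples).
#' @param topology lattice topology.
#' @param levels,wavelet,boundary wavelet decomposition settings (see
#'   [mdwt()]).
#' @param channel_id optional channel identifier carried as an attribute.
#' @return Integer matrix `6 x 1280` of class `channel_feature_set` (rows:
#'   categories; columns: 5 blocks of 256 bins in source order), with
#'   attributes `sources` and `channel_id`.
#' @export
extract_channel_features <- function(signal, topology = default_lattice(),
                                     levels = 4L, wavelet = "db4",
                                     boundary = "symmetric",
                                     channel_id = NA_integer_) {
  bands <- mdwt(signal, levels = levels, wavelet = wavelet,
                boundary = boundary, min_length = topology$n_vertices)
  sources <- c(list(signal), unname(bands$levels))
  mats <- lapply(sources, lattice123, topology = topology)
  out <- do.call(cbind, mats)
  dimnames(out) <- list(lattice_categories, NULL)
  structure(out, class = c("channel_feature_set", "matrix", "array"),
            sources = c("raw", names(bands$levels)),
            channel_id = channel_id)
}

#' Batch feature extraction over an epoch collection
#'
#' Runs [extract_channel_features()] on every (epoch, channel) pair and
#' reorganizes the result per channel and category, the layout consumed by
#' feature selection.
#'
#' @param collection an `epoch_collection` (see [epoch_collection()]).
#' @param channels channel indices to process (default all).
#' @param topology,levels,wavelet,boundary forwarded to
#'   [extract_channel_features()].
#' @param verbose print per-channel progress.
#' @return A list with one element per channel; each element is a list of 6
#'   integer matrices (epochs x 1280), named by category.
#' @export
extract_features <- function(collection, channels = NULL,
                             topology = default_lattice(), levels = 4L,
                             wavelet = "db4", boundary = "symmetric",
                             verbose = FALSE) {
  stopifnot(inherits(collection, "epoch_collection"))
  dims <- dim(collection$epochs)
  if (is.null(channels)) channels <- seq_len(dims[2L])
  n_ep <- dims[1L]
  out <- vector("list", length(channels))
  names(out) <- collection$channel_names[channels]
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    per_cat <- lapply(seq_len(6L), function(k)
      matrix(0L, nrow = n_ep, ncol = 5L * 256L))
    for (e in seq_len(n_ep)) {
      fs <- extract_channel_features(collection$epochs[e, ch, ],
                                     topology = topology, levels = levels,
                                     wavelet = wavelet, boundary = boundary,
                                     channel_id = ch)
      for (k in seq_len(6L)) per_cat[[k]][e, ] <- fs[k, ]
    }
    names(per_cat) <- lattice_categories
    out[[ci]] <- per_cat
    if (verbose)
      message("channel ", ch, " (", ci, "/", length(channels), ") done")
  }
  out
}

#' Write extracted features to disk
#'
#' One delimited matrix per (channel, category) pair (rows: epochs, columns:
#' the 1280 histogram bins) plus a JSON sidecar naming the categories,
#' sources and layout.
#'
#' @param features output of [extract_features()].
#' @param dir output directory (created if missing).
#' @return The sidecar path, invisibly.
#' @export
write_features <- function(features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(features))
    for (cat in names(features[[ch]])) {
      path <- file.path(dir, sprintf("features_%s_%s.csv", ch, cat))
      utils::write.table(features[[ch]][[cat]], path, sep = ",",
                         row.names = FALSE, col.names = FALSE)
    }
  sidecar <- file.path(dir, "features.json")
  jsonlite::write_json(list(
    categories = lattice_categories,
    sources = feature_sources,
    bins_per_source = 256L,
    vector_length = 1280L,
    channels = names(features),
    layout = "rows: epochs; columns: source-major blocks of 256 bins"
  ), sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}
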