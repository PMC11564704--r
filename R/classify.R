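with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Stratified cross-validation folds
#'
#' Assigns each observation to one of `k` folds, stratified by class so
#' every fold sees (near-)proportional class counts. If any class has fewer
#' members than folds, stratification is abandoned with a warning and a
#' plain shuffled assignment is used instead.
#'
#' @param y class labels.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the shuffle (assignment is deterministic given
#'   `seed`).
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(y, k = 10L, seed = 1L) {
  y <- as.factor(y)
  n <- length(y)
  if (n < k) stop("fewer observations than folds")
  fold <- integer(n)
  with_local_seed(seed, {
    if (min(table(y)) < k) {
      warning("a class has fewer than ", k,
              " members; falling back to non-stratified folds")
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    } else {
      for (cl in levels(y)) {
        idx <- which(y == cl)
        fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
      }
    }
  })
  fold
}

#' Out-of-fold 1-nearest-neighbour predictions
#'
#' Stratified k-fold cross-validation with a single nearest neighbour under
#' the city-block (L1) distance: each epoch is predicted by its nearest
#' neighbour among the training folds, and the out-of-fold predictions are
#' returned in epoch order. Distance ties resolve to the lowest-index
#' training row.
#'
#' @param x numeric feature matrix (epochs x features).
#' @param y class labels.
#' @param folds number of folds (default 10).
#' @param seed fold seed (ignored when `fold_id` is given).
#' @param fold_id optional explicit fold assignment.
#' @return Factor of predicted labels with the levels of `y`; the fold
#'   assignment is attached as attribute `fold_id`.
#' @export
knn_cv_predict <- function(x, y, folds = 10L, seed = 1L, fold_id = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nrow(x) != length(y)) stop("labels length mismatch")
  if (nlevels(droplevels(y)) < 2L) stop("need 2 classes")
  if (is.null(fold_id)) fold_id <- make_folds(y, k = folds, seed = seed)
  pred <- cpp_knn1_cv(x, as.integer(y), as.integer(fold_id))
  structure(factor(levels(y)[pred], levels = levels(y)), fold_id = fold_id)
}

#' Accuracy of a prediction vector
#'
#' @param predicted,truth label vectors of equal length.
#' @return Fraction of agreeing positions.
#' @export
prediction_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  mean(as.character(predicted) == as.character(truth))
}

#' Iterative hard majority voting
#'
#' Sorts the prediction vectors by accuracy (descending, stable) and, for
#' every committee size `r` from 3 up to `r_max`, takes the element-wise
#' mode over the top-`r` vectors. `np` inputs therefore yield `np - 2`
#' voted vectors (6 inputs give 4; 59 give 57). Mode ties resolve to the
#' label of the most accurate member vector holding a tied label, which is
#' deterministic and respects the accuracy ordering.
#'
#' @param predictions list of prediction vectors (equal length).
#' @param labels true labels, used to rank the inputs.
#' @param r_max largest committee size (default all inputs).
#' @return List of voted prediction vectors (factors); each carries
#'   attributes `r` (committee size) and `members` (indices into
#'   `predictions` of the committee, most accurate first).
#' @export
ihmv <- function(predictions, labels, r_max = NULL) {
  np <- length(predictions)
  if (np < 3L) stop("need at least 3 prediction vectors")
  if (is.null(r_max)) r_max <- np
  r_max <- min(r_max, np)
  labels <- as.factor(labels)
  lev <- levels(labels)
  acc <- vapply(predictions, prediction_accuracy, numeric(1L), truth = labels)
  ord <- order(acc, decreasing = TRUE) # stable: ties keep input order
  n <- length(labels)
  P <- vapply(predictions[ord],
              function(p) as.integer(factor(as.character(p), levels = lev)),
              integer(n))
  counts <- array(0L, dim = c(n, length(lev)))
  out <- vector("list", r_max - 2L)
  for (r in seq_len(r_max)) {
    counts[cbind(seq_len(n), P[, r])] <- counts[cbind(seq_len(n), P[, r])] + 1L
    if (r < 3L) next
    top <- apply(counts, 1L, max)
    chosen <- integer(n)
    unresolved <- rep(TRUE, n)
    for (m in seq_len(r)) { # members in accuracy order
      hit <- unresolved & counts[cbind(seq_len(n), P[, m])] == top
      chosen[hit] <- P[hit, m]
      unresolved <- unresolved & !hit
      if (!any(unresolved)) break
    }
    out[[r - 2L]] <- structure(factor(lev[chosen], levels = lev),
                               r = r, members = ord[seq_len(r)])
  }
  out
}

#' Greedy best-result selection
#'
#' Returns the candidate prediction vector with maximum accuracy against the
#' labels; ties go to the earliest candidate in the given ordering.
#'
#' @param candidates list of prediction vectors.
#' @param labels true labels.
#' @return A list: `vector`, `index`, `accuracy`, `accuracies` (all
#'   candidates).
#' @export
greedy_select <- function(candidates, labels) {
  if (!length(candidates)) stop("no candidates")
  acc <- vapply(candidates, prediction_accuracy, numeric(1L), truth = labels)
  idx <- unname(which.max(acc))
  list(vector = candidates[[idx]], index = idx, accuracy = unname(acc[idx]),
       accuracies = acc)
}

#' Full per-channel flow
#'
#' Runs the complete single-channel pipeline: multilevel feature extraction
#' for every epoch, iterative NCA selection and out-of-fold 1NN prediction
#' per category (all six categories share one fold assignment so their
#' out-of-fold predictions align), iterative hard majority voting over the
#' six predicted vectors, and greedy selection of the best among the ten
#' resulting candidates (six classifier vectors, then four voted vectors).
#'
#' @param x epochs x samples matrix for one channel.
#' @param labels per-epoch class labels.
#' @param channel_id identifier attached to results and error messages.
#' @param iv,fv,folds,seed,fold_id selection/classification settings (see
#'   [inca_select()]).
#' @param topology,levels,wavelet,boundary feature extraction settings.
#' @return A list of class `channel_result`: `channel_id`, `best_vector`,
#'   `best_accuracy`, `chosen_source`, `candidate_accuracies`,
#'   `predictions`, `voted`, `selections`.
#' @export
run_channel <- function(x, labels, channel_id = NA_integer_, iv = 100L,
                        fv = 512L, folds = 10L, seed = 1L, fold_id = NULL,
                        topology = default_lattice(), levels = 4L,
                        wavelet = "db4", boundary = "symmetric") {
  labels <- as.factor(labels)
  if (nrow(x) != length(labels)) stop("labels length mismatch")
  if (is.null(fold_id)) fold_id <- make_folds(labels, k = folds, seed = seed)
  res <- tryCatch({
    n_ep <- nrow(x)
    feats <- lapply(seq_len(6L), function(k)
      matrix(0L, nrow = n_ep, ncol = 5L * 256L))
    for (e in seq_len(n_ep)) {
      fs <- extract_channel_features(x[e, ], topology = topology,
                                     levels = levels, wavelet = wavelet,
                                     boundary = boundary,
                                     channel_id = channel_id)
      for (k in seq_len(6L)) feats[[k]][e, ] <- fs[k, ]
    }
    selections <- vector("list", 6L)
    predictions <- vector("list", 6L)
    for (k in seq_len(6L)) {
      sel <- inca_select(feats[[k]], labels, iv = iv, fv = fv,
                         fold_id = fold_id)
      predictions[[k]] <- knn_cv_predict(feats[[k]][, sel$indices,
                                                    drop = FALSE],
                                         labels, fold_id = fold_id)
      selections[[k]] <- sel
    }
    names(selections) <- names(predictions) <- lattice_categories
    voted <- ihmv(predictions, labels)
    candidates <- c(predictions, voted)
    names(candidates) <- c(lattice_categories,
                           paste0("voted_r", 3:(2L + length(voted))))
    best <- greedy_select(candidates, labels)
    structure(list(channel_id = channel_id, best_vector = best$vector,
                   best_accuracy = best$accuracy,
                   chosen_source = names(candidates)[best$index],
                   candidate_accuracies = stats::setNames(best$accuracies,
                                                          names(candidates)),
                   predictions = predictions, voted = voted,
                   selections = selections),
              class = "channel_result")
  }, error = function(e) {
    stop("channel ", channel_id, ": ", conditionMessage(e), call. = FALSE)
  })
  res
}

#' Overall fusion across channels
#'
#' Applies iterative hard majority voting to the channel-wise best
#' prediction vectors (nc inputs give nc - 2 voted vectors) and greedily
#' selects the most accurate among the union of channel vectors and voted
#' vectors (59 channels give 59 + 57 = 116 candidates). For a winning voted
#' vector, the committee channels are reported.
#'
#' @param channel_results list of `channel_result` objects (>= 3).
#' @param labels per-epoch class labels.
#' @return A list of class `overall_result`: `best_vector`, `accuracy`,
#'   `chosen` (candidate name), `n_candidates`, `contributing_channels`,
#'   `channel_accuracies`.
#' @export
run_overall <- function(channel_results, labels) {
  if (length(channel_results) < 3L) stop("need at least 3 channel results")
  labels <- as.factor(labels)
  bests <- lapply(channel_results, `[[`, "best_vector")
  ids <- vapply(channel_results, `[[`, numeric(1L), "channel_id")
  voted <- ihmv(bests, labels)
  candidates <- c(bests, voted)
  names(candidates) <- c(paste0("channel_", ids),
                         paste0("voted_r", 3:(2L + length(voted))))
  best <- greedy_select(candidates, labels)
  contributing <- if (best$index <= length(bests)) {
    ids[best$index]
  } else {
    ids[attr(candidates[[best$index]], "members")]
  }
  structure(list(best_vector = best$vector, accuracy = best$accuracy,
                 chosen = names(candidates)[best$index],
                 n_candidates = length(candidates),
                 contributing_channels = contributing,
                 candidate_accuracies = stats::setNames(best$accuracies,
                                                        names(candidates)),
                 channel_accuracies = stats::setNames(
                   vapply(channel_results, `[[`, numeric(1L),
                          "best_accuracy"), paste0("channel_", ids))),
            class = "overall_result")
}

#' End-to-end pipeline over an epoch collection
#'
#' Runs [run_channel()] for every channel (one shared stratified fold
#' assignment for the whole run) followed by [run_overall()], and computes
#' the metric report of the overall best prediction vector. With fewer than
#' three channels no voting committee can form and the overall stage
#' reduces to greedy selection over the channel winners.
#'
#' @param collection an `epoch_collection`.
#' @param iv,fv,folds,seed pipeline settings (defaults 100, 512, 10).
#' @param topology,levels,wavelet,boundary feature extraction settings.
#' @param verbose print per-channel progress.
#' @return A list of class `lattice_run`: `channels` (list of
#'   `channel_result`), `overall`, `metrics`, `fold_id`, `settings`.
#' @export
lattice_run <- function(collection, iv = 100L, fv = 512L, folds = 10L,
                        seed = 1L, topology = default_lattice(), levels = 4L,
                        wavelet = "db4", boundary = "symmetric",
                        verbose = FALSE) {
  stopifnot(inherits(collection, "epoch_collection"))
  labels <- as.factor(collection$labels)
  fold_id <- make_folds(labels, k = folds, seed = seed)
  nch <- dim(collection$epochs)[2L]
  t0 <- proc.time()[["elapsed"]]
  channels <- vector("list", nch)
  for (ch in seq_len(nch)) {
    channels[[ch]] <- run_channel(collection$epochs[, ch, ], labels,
                                  channel_id = ch, iv = iv, fv = fv,
                                  fold_id = fold_id, topology = topology,
                                  levels = levels, wavelet = wavelet,
                                  boundary = boundary)
    if (verbose)
      message("channel ", ch, "/", nch, ": accuracy ",
              sprintf("%.4f", channels[[ch]]$best_accuracy),
              " (", channels[[ch]]$chosen_source, ")")
  }
  overall <- if (nch >= 3L) {
    run_overall(channels, labels)
  } else {
    # too few channels for a voting committee: greedy over channel winners
    bests <- lapply(channels, `[[`, "best_vector")
    best <- greedy_select(bests, labels)
    structure(list(best_vector = best$vector, accuracy = best$accuracy,
                   chosen = paste0("channel_", best$index),
                   n_candidates = nch,
                   contributing_channels = best$index,
                   candidate_accuracies = best$accuracies,
                   channel_accuracies = vapply(channels, `[[`, numeric(1L),
                                               "best_accuracy")),
              class = "overall_result")
  }
  structure(list(channels = channels, overall = overall,
                 metrics = compute_metrics(overall$best_vector, labels),
                 fold_id = fold_id,
                 settings = list(iv = iv, fv = fv, folds = folds, seed = seed,
                                 levels = levels, wavelet = wavelet,
                                 boundary = boundary),
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "lattice_run")
}

#' @export
print.lattice_run <- function(x, ...) {
  cat("Lattice pattern run: ", length(x$channels), " channels, ",
      length(x$overall$best_vector), " epochs\n", sep = "")
  cat("Overall best: ", x$overall$chosen, ", accuracy ",
      sprintf("%.2f%%", 100 * x$overall$accuracy), "\n", sep = "")
  invisible(x)
}
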