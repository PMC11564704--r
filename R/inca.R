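#' Neighborhood component analysis feature ranking
#'
#' Learns one non-negative relevance weight per feature column by maximizing
#' the regularized leave-one-out NCA objective under a diagonal weighted
#' city-block metric
#' \eqn{d_w(x_i, x_j) = \sum_d w_d^2 |x_{id} - x_{jd}|}, and ranks columns
#' by descending weight. Columns are z-scored internally for weight
#' learning only; constant columns get weight zero. Optimization is batch
#' gradient ascent from a unit start with an adaptive step, so the result
#' is deterministic.
#'
#' @param x numeric matrix, observations x features.
#' @param y class labels (factor or coercible; >= 2 classes, and at least
#'   one class with >= 2 observations).
#' @param lambda regularization weight; default `1 / nrow(x)`.
#' @param max_iter maximum objective evaluations (default 40).
#' @param tol relative convergence tolerance on the objective.
#' @return A list of class `nca_ranking`: `order` (column indices, best
#'   first), `weights` (per input column), `objective` (ascent trace).
#' @export
nca_rank <- function(x, y, lambda = NULL, max_iter = 40L, tol = 1e-6) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nrow(x) != length(y)) stop("labels length mismatch")
  if (nlevels(droplevels(y)) < 2L) stop("need at least 2 classes")
  if (max(table(y)) < 2L)
    stop("degenerate input: every class has a single observation")
  if (is.null(lambda)) lambda <- 1 / nrow(x)
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  keep <- sdev > 0
  z <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdev[keep], "/")
  fit <- cpp_nca_weights(z, as.integer(y), lambda, as.integer(max_iter), tol)
  w <- numeric(ncol(x))
  w[keep] <- fit$weights
  ord <- order(w, decreasing = TRUE)
  structure(list(order = ord, weights = w, objective = fit$objective),
            class = "nca_ranking")
}

#' Iterative NCA feature selection
#'
#' Ranks the columns with [nca_rank()], then sweeps nested prefixes of the
#' ranking: for every candidate size `v` in `iv..min(fv, ncol(x))` the
#' out-of-fold accuracy of a city-block 1-nearest-neighbour classifier under
#' stratified k-fold cross-validation is evaluated on the top-`v` columns.
#' The prefix with maximum accuracy wins; ties go to the smallest size
#' (parsimony). The classifier consumes the unstandardized selected
#' columns; the same fold assignment is reused by the downstream
#' classification stage when `fold_id` is shared.
#'
#' @param x numeric matrix, observations x features (`ncol(x) >= iv`).
#' @param y class labels.
#' @param iv,fv first and last candidate prefix sizes (defaults 100 and 512;
#'   `fv` is silently truncated at `ncol(x)`).
#' @param folds number of cross-validation folds (default 10).
#' @param seed fold-assignment seed (ignored when `fold_id` is given).
#' @param fold_id optional explicit fold assignment (integer per row).
#' @param ranking optional precomputed `nca_ranking`.
#' @return A list of class `inca_selection`: `indices` (selected columns, a
#'   prefix of the ranking), `size`, `cv_accuracy`, `accuracy_curve` (named
#'   by candidate size), `ranking`, `fold_id`.
#' @export
inca_select <- function(x, y, iv = 100L, fv = 512L, folds = 10L, seed = 1L,
                        fold_id = NULL, ranking = NULL) {
  x <- as.matrix(x)
  y <- as.factor(y)
  iv <- as.integer(iv); fv <- as.integer(fv)
  if (iv < 1L || fv < iv) stop("need 1 <= iv <= fv")
  if (ncol(x) < iv)
    stop("only ", ncol(x), " feature columns but iv = ", iv,
         "; use a smaller iv")
  fv <- min(fv, ncol(x))
  if (is.null(ranking)) ranking <- nca_rank(x, y)
  if (is.null(fold_id)) fold_id <- make_folds(y, k = folds, seed = seed)
  ord <- ranking$order[seq_len(fv)]
  acc <- cpp_prefix_cv_acc(x[, ord, drop = FALSE], as.integer(y),
                           as.integer(fold_id), iv)
  sizes <- iv:fv
  best <- which.max(acc) # first maximum: smallest size on ties
  size <- sizes[best]
  structure(list(indices = ranking$order[seq_len(size)], size = size,
                 cv_accuracy = acc[best],
                 accuracy_curve = stats::setNames(as.numeric(acc), sizes),
                 ranking = ranking, fold_id = fold_id),
            class = "inca_selection")
}

#' @export
print.inca_selection <- function(x, ...) {
  cat("INCA selection: ", x$size, " features, CV accuracy ",
      sprintf("%.4f", x$cv_accuracy), "\n", sep = "")
  invisible(x)
}

#' Export a selection run as JSON
#'
#' Writes ranked indices, weights, the accuracy-vs-size curve and the chosen
#' size, the quantities behind selection-diagnostic reporting.
#'
#' @param selection an `inca_selection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(list(
    ranked_indices = selection$ranking$order,
    weights = selection$ranking$weights,
    sizes = as.integer(names(selection$accuracy_curve)),
    accuracy_curve = as.numeric(selection$accuracy_curve),
    selected_size = selection$size,
    cv_accuracy = selection$cv_accuracy
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
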