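round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Geometric mean of two class-wise sensitivities
#'
#' \eqn{\sqrt{sens_1 \times sens_2}}: equivalently the square root of
#' sensitivity times specificity of either class taken as positive. The
#' preferred summary for imbalanced two-class problems, since it cannot be
#' inflated by majority-class accuracy.
#'
#' @param sens1,sens2 the two class-wise sensitivities (same scale, e.g.
#'   percent).
#' @return The geometric mean on the input scale.
#' @examples
#' geometric_mean(93.97, 99.60) # 96.74...
#' @export
geometric_mean <- function(sens1, sens2) sqrt(sens1 * sens2)

#' F1 score from precision and recall
#'
#' @param precision,recall same-scale rates.
#' @return Harmonic mean `2 * p * r / (p + r)`.
#' @examples
#' f1_score(98.49, 93.97) # 96.17...
#' @export
f1_score <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' Confusion matrix and metric suite
#'
#' Computes the 2x2 confusion matrix (rows: truth, columns: predicted) and,
#' per class, sensitivity, specificity, precision and F1 in percent,
#' together with overall accuracy, unweighted (macro) means of the
#' class-wise rates, and the geometric mean of the two class-wise
#' sensitivities. Raw fractions are retained; the print method rounds
#' half-up to two decimals.
#'
#' @param predicted predicted labels; every level must occur in `truth`'s
#'   class set.
#' @param truth true labels (2 classes).
#' @return A list of class `metrics_report`: `confusion`, `per_class` (data
#'   frame of percents), `accuracy`, `macro` (named vector), and
#'   `geometric_mean` (all percents).
#' @export
compute_metrics <- function(predicted, truth) {
  truth <- as.factor(truth)
  lev <- levels(droplevels(truth))
  predicted <- as.character(predicted)
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (!all(predicted %in% lev))
    stop("prediction contains labels unseen in the truth: ",
         paste(setdiff(unique(predicted), lev), collapse = ", "))
  predicted <- factor(predicted, levels = lev)
  truth <- factor(as.character(truth), levels = lev)
  cm <- table(truth = truth, predicted = predicted)
  n <- sum(cm)
  per <- t(vapply(lev, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
          else 2 * prec * sens / (prec + sens)
    100 * c(sensitivity = sens, specificity = spec, precision = prec,
            f1 = f1)
  }, numeric(4L)))
  per <- as.data.frame(per)
  rownames(per) <- lev
  macro <- colMeans(per)
  structure(list(
    confusion = cm,
    per_class = per,
    accuracy = 100 * sum(diag(cm)) / n,
    macro = macro,
    geometric_mean = geometric_mean(per$sensitivity[1L],
                                    per$sensitivity[2L])),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion matrix (rows: truth):\n")
  print(x$confusion)
  fmt <- function(v) sprintf("%.2f", round_half_up(v))
  cat("\nPer class (%):\n")
  print(as.data.frame(lapply(x$per_class, round_half_up),
                      row.names = rownames(x$per_class)))
  cat("\nOverall accuracy: ", fmt(x$accuracy),
      "%\nMacro sensitivity/specificity/precision/F1: ",
      paste(fmt(x$macro), collapse = " / "),
      "\nGeometric mean: ", fmt(x$geometric_mean), "%\n", sep = "")
  invisible(x)
}

#' Write a metric report to disk
#'
#' The confusion matrix goes to a labeled CSV; all rates (raw fractions of
#' percent, unrounded) to a JSON file alongside.
#'
#' @param report a `metrics_report`.
#' @param prefix path prefix; writes `<prefix>_confusion.csv` and
#'   `<prefix>_metrics.json`.
#' @return The JSON path, invisibly.
#' @export
write_metrics <- function(report, prefix) {
  cm <- as.data.frame.matrix(report$confusion)
  utils::write.csv(cm, paste0(prefix, "_confusion.csv"))
  path <- paste0(prefix, "_metrics.json")
  jsonlite::write_json(list(
    per_class = cbind(class = rownames(report$per_class), report$per_class),
    accuracy = report$accuracy,
    macro = as.list(report$macro),
    geometric_mean = report$geometric_mean
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
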