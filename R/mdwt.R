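# Daubechies-4 (8-tap) decomposition/reconstruction filters, standard
# published coefficients (sum(dec_lo) = sqrt(2)).
.db4_dec_lo <- c(-0.010597401785069032, 0.0328830116668852,
                 0.030841381835560764, -0.18703481171909309,
                 -0.027983769416859854, 0.6308807679298589,
                 0.7148465705529157, 0.2303778133088965)
.db4_dec_hi <- c(-0.2303778133088965, 0.7148465705529157,
                 -0.6308807679298589, -0.027983769416859854,
                 0.18703481171909309, 0.030841381835560764,
                 -0.0328830116668852, -0.010597401785069032)
.db4_rec_lo <- rev(.db4_dec_lo)
.db4_rec_hi <- rev(.db4_dec_hi)

wavelet_filters <- function(wavelet) {
  if (!identical(wavelet, "db4"))
    stop("unsupported wavelet '", wavelet, "' (only db4 is provided)")
  list(dec_lo = .db4_dec_lo, dec_hi = .db4_dec_hi,
       rec_lo = .db4_rec_lo, rec_hi = .db4_rec_hi)
}

extend_signal <- function(x, p, boundary) {
  switch(boundary,
         symmetric = c(rev(x[seq_len(min(p, length(x)))]),
                       x,
                       rev(x)[seq_len(min(p, length(x)))]),
         zero = c(numeric(p), x, numeric(p)),
         stop("unsupported boundary mode '", boundary, "'"))
}

#' Single-level discrete wavelet transform
#'
#' One analysis step: the signal is boundary-extended, convolved with the
#' low- and high-pass decomposition filters and downsampled by two. The
#' default boundary mode is half-point symmetric extension (the edge sample
#' is repeated), under which the output length is
#' \eqn{\lfloor (n + 7) / 2 \rfloor} for the 8-tap db4 filters.
#'
#' @param x numeric signal (length >= 2).
#' @param wavelet wavelet name; only `"db4"` is shipped.
#' @param boundary `"symmetric"` (half-point) or `"zero"`.
#' @return A list with `approx` and `detail` coefficient vectors.
#' @seealso [idwt_level()] for the exact inverse, [mdwt()] for the
#'   multilevel low-pass cascade.
#' @export
dwt_level <- function(x, wavelet = "db4", boundary = "symmetric") {
  f <- wavelet_filters(wavelet)
  p <- length(f$dec_lo) - 1L
  if (length(x) < 2L) stop("signal too short for one DWT level")
  ext <- extend_signal(x, p, boundary)
  # sides=1 filter() computes sum_j c[j] * ext[t - j + 1]: true convolution;
  # the first p outputs are NA (incomplete support)
  lo <- stats::filter(ext, f$dec_lo, method = "convolution", sides = 1L)
  hi <- stats::filter(ext, f$dec_hi, method = "convolution", sides = 1L)
  keep <- seq.int(p + 2L, length(ext), by = 2L)
  list(approx = as.numeric(lo[keep]), detail = as.numeric(hi[keep]))
}

#' Single-level inverse discrete wavelet transform
#'
#' Exact inverse of [dwt_level()]: upsample both coefficient sequences,
#' convolve with the reconstruction filters, sum, and trim the boundary
#' transient down to the original length.
#'
#' @param approx,detail coefficient vectors from [dwt_level()].
#' @param n original signal length.
#' @param wavelet wavelet name.
#' @return Numeric vector of length `n`.
#' @export
idwt_level <- function(approx, detail, n, wavelet = "db4") {
  f <- wavelet_filters(wavelet)
  flen <- length(f$rec_lo)
  up <- function(v) {
    u <- numeric(2L * length(v))
    u[seq.int(1L, by = 2L, length.out = length(v))] <- v
    u
  }
  conv_full <- function(a, b) {
    # full linear convolution via convolve()
    stats::convolve(a, rev(b), type = "open")
  }
  rec <- conv_full(up(approx), f$rec_lo) + conv_full(up(detail), f$rec_hi)
  rec[(flen - 1L):(flen - 2L + n)]
}

#' Multilevel low-pass wavelet decomposition
#'
#' Cascade of single-level DWTs: each level decomposes the previous
#' approximation; the high-pass (detail) outputs are computed and dropped.
#' The returned approximation subbands L1..L4 (with the raw signal) are the
#' five sources of the multilevel feature extraction.
#'
#' @param x numeric signal.
#' @param levels number of levels (default 4).
#' @param wavelet wavelet name (default `"db4"`).
#' @param boundary boundary-extension mode (default `"symmetric"`).
#' @param min_length smallest admissible final-level length; the input must
#'   be long enough that the last approximation still holds at least this
#'   many samples (19, one lattice block, by default).
#' @return An object of class `wavelet_band_set`: list with `levels` (list
#'   `L1`..`L4`), `wavelet`, `boundary`.
#' @examples
#' b <- mdwt(rnorm(3750))
#' lengths(b$levels) # 1878 942 474 240
#' @export
mdwt <- function(x, levels = 4L, wavelet = "db4", boundary = "symmetric",
                 min_length = 19L) {
  if (!is.numeric(x) || any(!is.finite(x))) stop("signal must be finite numeric")
  # minimum input length so the last level keeps >= min_length samples
  need <- min_length
  for (h in seq_len(levels)) need <- 2L * need - 7L
  if (length(x) < need)
    stop("signal too short for ", levels, "-level decomposition: need >= ",
         need, " samples so the final subband keeps >= ", min_length)
  out <- vector("list", levels)
  cur <- x
  for (h in seq_len(levels)) {
    dec <- dwt_level(cur, wavelet, boundary)
    cur <- dec$approx
    out[[h]] <- cur
  }
  names(out) <- paste0("L", seq_len(levels))
  structure(list(levels = out, wavelet = wavelet, boundary = boundary),
            class = "wavelet_band_set")
}

#' @export
print.wavelet_band_set <- function(x, ...) {
  cat("Wavelet band set (", x$wavelet, ", ", x$boundary, " boundary): ",
      paste0(names(x$levels), "[", lengths(x$levels), "]", collapse = " "),
      "\n", sep = "")
  invisible(x)
}
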