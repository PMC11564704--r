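#' Min-max normalization to integers 1..100
#'
#' Maps a signal onto the integer range 1..100 by
#' \eqn{\lceil 99 (x - x_{min}) / (x_{max} - x_{min}) \rceil + 1}, so the
#' minimum maps to 1 and the maximum to 100. A constant signal maps to all
#' ones (the scale is undefined there and the low end is the convention).
#' The normalized values index the value-probability table that drives the
#' lattice walks; the raw values are what the comparison kernels see.
#'
#' @param signal numeric vector, finite, length >= 1.
#' @return Integer vector in 1..100, same length as `signal`.
#' @examples
#' normalize_signal(c(0, 5, 10)) # 1 51 100
#' @export
normalize_signal <- function(signal) {
  if (length(signal) < 1L) stop("empty signal")
  if (!is.numeric(signal) || any(!is.finite(signal)))
    stop("signal must be finite numeric")
  rng <- range(signal)
  if (rng[1L] == rng[2L]) return(rep(1L, length(signal)))
  as.integer(ceiling((signal - rng[1L]) / (rng[2L] - rng[1L]) * 99)) + 1L
}

#' Probability of each normalized value
#'
#' Relative frequency of each of the 100 normalized values over the whole
#' signal. These per-value probabilities, looked up block-wise, are what the
#' greedy walks minimize or maximize.
#'
#' @param normalized integer vector of normalized values (1..100).
#' @return Numeric vector of length 100 summing to 1.
#' @export
value_probabilities <- function(normalized) {
  if (length(normalized) < 1L) stop("empty input")
  if (any(normalized < 1L | normalized > 100L))
    stop("normalized values must lie in 1..100")
  tabulate(normalized, nbins = 100L) / length(normalized)
}

#' Overlapping 19-sample blocks of a signal
#'
#' Slides a window of one sample stride across the signal; block \eqn{i}
#' covers samples \eqn{i..i+18}. Each block populates the 19 lattice
#' vertices in order.
#'
#' @param signal numeric vector, length >= `size`.
#' @param normalized matching normalized values (defaults to
#'   `normalize_signal(signal)`).
#' @param size block length (the number of lattice vertices).
#' @return A list of blocks; each block is a list with `raw`, `normalized`
#'   and `start_index`.
#' @export
signal_blocks <- function(signal, normalized = normalize_signal(signal),
                          size = 19L) {
  n <- length(signal)
  if (n < size)
    stop("signal shorter than one block (need >= ", size, " samples)")
  if (length(normalized) != n)
    stop("normalized values must align with the signal")
  lapply(seq_len(n - size + 1L), function(i) {
    idx <- i:(i + size - 1L)
    list(raw = signal[idx], normalized = normalized[idx], start_index = i)
  })
}

#' Vertex probabilities for one block
#'
#' Vertex \eqn{j} receives the global probability of the block's \eqn{j}-th
#' normalized value: the vertices are populated sequentially by the block.
#'
#' @param block a block from [signal_blocks()].
#' @param table probability table from [value_probabilities()].
#' @return Numeric vector, one probability per vertex.
#' @export
block_vertex_probabilities <- function(block, table) {
  table[block$normalized]
}

#' Comparison kernels
#'
#' The three binary comparison kernels applied along a walking path:
#' signum fires when \eqn{a - b \ge 0}; upper ternary when \eqn{a - b > tr};
#' lower ternary when \eqn{a - b < -tr}. `tr` is the ternary threshold, half
#' the population standard deviation of the signal being transformed (see
#' [ternary_threshold()]).
#'
#' @param a,b numeric, the two compared signal values (vectorized).
#' @param tr non-negative ternary threshold.
#' @return Integer 0/1 of the common length of `a` and `b`.
#' @examples
#' kernel_signum(4, 4)             # 1
#' kernel_upper_ternary(5, 3, 1)   # 1
#' kernel_lower_ternary(3, 5, 1)   # 1
#' @export
kernel_signum <- function(a, b) as.integer(a - b >= 0)

#' @rdname kernel_signum
#' @export
kernel_upper_ternary <- function(a, b, tr) {
  if (any(tr < 0)) stop("tr must be non-negative")
  as.integer(a - b > tr)
}

#' @rdname kernel_signum
#' @export
kernel_lower_ternary <- function(a, b, tr) {
  if (any(tr < 0)) stop("tr must be non-negative")
  as.integer(a - b < -tr)
}

#' Ternary threshold of a signal
#'
#' Half the population standard deviation (divisor \eqn{n}, not \eqn{n-1})
#' of the whole signal being transformed. Computed once per input signal:
#' the raw epoch and each wavelet subband get their own threshold.
#'
#' @param signal numeric vector, length >= 2.
#' @return A single non-negative number.
#' @export
ternary_threshold <- function(signal) {
  if (length(signal) < 2L) stop("need at least 2 samples")
  sqrt(mean((signal - mean(signal))^2)) / 2
}

#' Kernel bits along a walking path
#'
#' Applies one kernel to the 8 consecutive vertex pairs of a 9-vertex walk:
#' bit \eqn{t} compares the block's raw values at path positions \eqn{t} and
#' \eqn{t+1}.
#'
#' @param block a block from [signal_blocks()].
#' @param path a 9-vertex walking path.
#' @param kernel `"signum"`, `"upper"` or `"lower"`.
#' @param tr ternary threshold (ignored by signum).
#' @return Integer vector of 8 bits.
#' @export
extract_bits <- function(block, path, kernel = c("signum", "upper", "lower"),
                         tr = 0) {
  kernel <- match.arg(kernel)
  path <- as.integer(path)
  a <- block$raw[path[-length(path)]]
  b <- block$raw[path[-1L]]
  switch(kernel,
         signum = kernel_signum(a, b),
         upper = kernel_upper_ternary(a, b, tr),
         lower = kernel_lower_ternary(a, b, tr))
}

#' Binary-to-decimal map value
#'
#' Bit 1 is the least significant: the value is
#' \eqn{\sum_t bit_t 2^{t-1}}, in 0..255 for 8 bits.
#'
#' @param bits integer vector of 8 bits.
#' @return Integer scalar.
#' @export
bits_to_decimal <- function(bits) {
  if (length(bits) != 8L) stop("expected 8 bits")
  if (any(!bits %in% c(0L, 1L))) stop("bits must be 0 or 1")
  as.integer(sum(bits * 2L^(seq_along(bits) - 1L)))
}

lattice_categories <- c("min_signum", "max_signum", "min_upper",
                        "min_lower", "max_upper", "max_lower")

#' The lattice graph pattern transform
#'
#' Full dynamic-graph textural transform of a one-dimensional signal. The
#' signal is normalized to 1..100 and the relative frequency of each
#' normalized value is computed. For every overlapping 19-sample block, the
#' lattice vertices take the probabilities of the block's values and two
#' greedy walks (minimum and maximum probability) are traced from source to
#' sink. Along each walk the three comparison kernels (signum, upper
#' ternary, lower ternary) produce 8-bit codes, giving six map signals with
#' values 0..255 whose 256-bin histograms are the six feature vectors.
#'
#' Category order is fixed: 1 (min, signum), 2 (max, signum),
#' 3 (min, upper), 4 (min, lower), 5 (max, upper), 6 (max, lower).
#'
#' @param signal numeric vector, length >= 19.
#' @param topology lattice topology (default [default_lattice()]).
#' @param return_maps also return the six integer map signals.
#' @return Integer matrix `6 x 256` of class `lattice123_features` (rows:
#'   categories, columns: bins 0..255; each row sums to `length(signal) -
#'   18`). If `return_maps`, the map signals are attached as attribute
#'   `maps` (an `(n-18) x 6` matrix).
#' @examples
#' h <- lattice123(sin(seq_len(200)))
#' dim(h)        # 6 256
#' rowSums(h)    # all 182
#' @export
lattice123 <- function(signal, topology = default_lattice(),
                       return_maps = FALSE) {
  if (!is.numeric(signal) || any(!is.finite(signal)))
    stop("signal must be finite numeric")
  nv <- topology$n_vertices
  if (length(signal) < nv)
    stop("signal shorter than one block (need >= ", nv, " samples)")
  norm <- normalize_signal(signal)
  pr <- value_probabilities(norm)
  tr <- ternary_threshold(signal)
  maps <- cpp_lattice_maps(as.numeric(signal), norm, pr,
                           children_list(topology), tr)
  h <- vapply(seq_len(6L),
              function(k) tabulate(maps[, k] + 1L, nbins = 256L),
              integer(256L))
  h <- t(h)
  dimnames(h) <- list(lattice_categories, NULL)
  out <- structure(h, class = c("lattice123_features", "matrix", "array"))
  if (return_maps) attr(out, "maps") <- maps
  out
}
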