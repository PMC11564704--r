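test_that("normalization maps onto 1..100 with the documented conventions", {
  expect_identical(normalize_signal(c(7, 7, 7)), c(1L, 1L, 1L))
  expect_identical(normalize_signal(c(0, 5, 10)), c(1L, 51L, 100L))
  set.seed(21)
  for (rep in 1:20) {
    x <- rnorm(50)
    nv <- normalize_signal(x)
    expect_true(all(nv >= 1L & nv <= 100L))
    expect_identical(nv[which.min(x)], 1L)
    expect_identical(nv[which.max(x)], 100L)
  }
  expect_error(normalize_signal(numeric(0)), "empty")
  expect_error(normalize_signal(c(1, NaN)), "finite")
  expect_error(normalize_signal(c(1, Inf)), "finite")
})

test_that("value probabilities are counting frequencies over 100 bins", {
  expect_equal(value_probabilities(1:100), rep(0.01, 100))
  p <- value_probabilities(c(1L, 1L, 1L, 100L))
  expect_equal(p[1], 0.75)
  expect_equal(p[100], 0.25)
  expect_equal(sum(p[2:99]), 0)
  set.seed(22)
  for (rep in 1:10)
    expect_equal(sum(value_probabilities(sample(1:100, 37, TRUE))), 1,
                 tolerance = 1e-12)
})

test_that("block iteration is a stride-1 window of length 19", {
  expect_length(signal_blocks(rnorm(19)), 1L)
  x <- rnorm(100)
  b <- signal_blocks(x)
  expect_length(b, 82L)
  k <- 37L
  expect_identical(b[[k]]$raw, x[k:(k + 18L)])
  expect_identical(b[[k]]$start_index, k)
  expect_error(signal_blocks(rnorm(18)), "shorter than one block")
})

test_that("a length-3750 epoch yields 3732 blocks", {
  expect_length(signal_blocks(rnorm(3750)), 3732L)
})

test_that("vertex probabilities are sequential value lookups", {
  x <- rep(2.5, 30)
  tab <- value_probabilities(normalize_signal(x))
  b <- signal_blocks(x)[[1]]
  expect_equal(block_vertex_probabilities(b, tab), rep(1, 19))
  set.seed(23)
  x <- rnorm(60)
  nv <- normalize_signal(x)
  tab <- value_probabilities(nv)
  b <- signal_blocks(x, nv)[[10]]
  expect_equal(block_vertex_probabilities(b, tab), tab[nv[10:28]])
  # identical normalized content => identical assignment
  b2 <- signal_blocks(x, nv)[[10]]
  expect_identical(block_vertex_probabilities(b, tab),
                   block_vertex_probabilities(b2, tab))
})

test_that("kernels implement the signum and ternary comparisons", {
  expect_identical(kernel_signum(5, 3), 1L)
  expect_identical(kernel_signum(3, 5), 0L)
  expect_identical(kernel_signum(4, 4), 1L) # boundary belongs to 1
  expect_identical(kernel_upper_ternary(5, 3, 1), 1L)
  expect_identical(kernel_lower_ternary(5, 3, 1), 0L)
  expect_identical(kernel_upper_ternary(3, 5, 1), 0L)
  expect_identical(kernel_lower_ternary(3, 5, 1), 1L)
  expect_error(kernel_upper_ternary(1, 2, -0.5), "non-negative")
  expect_error(kernel_lower_ternary(1, 2, -0.5), "non-negative")
  # with tr = 0 exactly one of upper/lower fires whenever a != b
  for (a in -2:2) for (b in -2:2) {
    fired <- kernel_upper_ternary(a, b, 0) + kernel_lower_ternary(a, b, 0)
    expect_identical(fired, as.integer(a != b))
  }
})

test_that("ternary threshold is half the population standard deviation", {
  expect_identical(ternary_threshold(rep(3, 10)), 0)
  expect_equal(ternary_threshold(c(0, 0, 10, 10)), 2.5)
  set.seed(24)
  x <- rnorm(40)
  expect_equal(ternary_threshold(3 * x), 3 * ternary_threshold(x))
  expect_equal(ternary_threshold(x + 100), ternary_threshold(x))
  expect_error(ternary_threshold(5), "at least 2")
})

test_that("bit extraction walks the path pairwise", {
  topo <- default_lattice()
  path <- enumerate_paths(topo)[[1]]
  inc <- signal_blocks(seq_len(19) + 0)[[1]]
  expect_identical(extract_bits(inc, path, "signum"), rep(0L, 8))
  const <- signal_blocks(rep(4, 19))[[1]]
  expect_identical(extract_bits(const, path, "signum"), rep(1L, 8))
  set.seed(25)
  b <- signal_blocks(rnorm(19))[[1]]
  for (k in c("signum", "upper", "lower"))
    expect_length(extract_bits(b, path, k, tr = 0.3), 8L)
})

test_that("binary-to-decimal uses bit 1 as least significant", {
  expect_identical(bits_to_decimal(c(1, 0, 0, 0, 0, 0, 0, 0)), 1L)
  expect_identical(bits_to_decimal(rep(1L, 8)), 255L)
  expect_identical(bits_to_decimal(c(0, 1, 0, 1, 0, 0, 0, 0)), 10L)
  expect_error(bits_to_decimal(c(1, 0, 1)), "8 bits")
  expect_error(bits_to_decimal(c(1, 0, 2, 0, 0, 0, 0, 0)), "0 or 1")
})
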