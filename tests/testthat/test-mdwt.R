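# Frozen reference coefficients for the cascade, computed independently with
# PyWavelets 1.9 (db4, 'symmetric' mode) on the fixed signal below.
pywt_fixture <- function() {
  x <- c(0.49671400, -0.13826400, 0.64768900, 1.52303000, -0.23415300, -0.23413700,
         1.57921300, 0.76743500, -0.46947400, 0.54256000, -0.46341800, -0.46573000,
         0.24196200, -1.91328000, -1.72491800, -0.56228800, -1.01283100, 0.31424700,
         -0.90802400, -1.41230400, 1.46564900, -0.22577600, 0.06752800, -1.42474800,
         -0.54438300, 0.11092300, -1.15099400, 0.37569800, -0.60063900, -0.29169400,
         -0.60170700, 1.85227800, -0.01349700, -1.05771100, 0.82254500, -1.22084400,
         0.20886400, -1.95967000, -1.32818600, 0.19686100, 0.73846700, 0.17136800,
         -0.11564800, -0.30110400, -1.47852200, -0.71984400, -0.46063900, 1.05712200,
         0.34361800, -1.76304000, 0.32408400, -0.38508200, -0.67692200, 0.61167600,
         1.03100000, 0.93128000, -0.83921800, -0.30921200, 0.33126300, 0.97554500,
         -0.47917400, -0.18565900, -1.10633500, -1.19620700)
  L1 <- c(0.78038034, 0.62073329, 0.56107135, 0.46195887, 0.80388886,
          0.84774193, 0.70159270, -0.15466308, 0.03514608, -2.20020697,
          -1.27023962, -0.80580017, -0.36344916, 0.32213977, -1.13926071,
          -0.71884538, -0.18693381, -0.76844078, 1.04269680, -0.35138359,
          -0.21965735, -2.32962741, 0.26718389, 0.45607832, -1.00577157,
          -1.27929262, 0.81444466, -0.79640058, -0.83321696, 1.05366517,
          0.33678852, -0.17249502, 0.61899429, -0.71901543, -1.78516944)
  L4 <- c(1.82608370, 1.86188088, 1.81245371, 1.78154462, 2.31464839,
          0.06169805, -1.23302090, -1.43626754, -0.11632462, -4.56105049)
  list(x = x, L1 = L1, L4 = L4)
}

test_that("the db4 cascade matches the frozen independent reference", {
  fx <- pywt_fixture()
  bands <- mdwt(fx$x, levels = 4, min_length = 2L)
  expect_equal(bands$levels$L1, fx$L1, tolerance = 1e-6)
  expect_equal(bands$levels$L4, fx$L4, tolerance = 1e-6)
})

test_that("subband lengths follow the halving recursion for a 3750 epoch", {
  bands <- mdwt(rnorm(3750))
  expect_identical(unname(lengths(bands$levels)), c(1878L, 942L, 474L, 240L))
  expect_true(all(lengths(bands$levels) >= 19L))
})

test_that("decomposition is linear and recursive", {
  set.seed(41)
  x <- rnorm(400); y <- rnorm(400)
  bx <- mdwt(x); by <- mdwt(y)
  bz <- mdwt(2 * x - 3 * y)
  for (h in 1:4)
    expect_equal(bz$levels[[h]], 2 * bx$levels[[h]] - 3 * by$levels[[h]],
                 tolerance = 1e-10)
  # zero in, zero out
  b0 <- mdwt(numeric(400))
  expect_true(all(unlist(b0$levels) == 0))
  # level 4 equals a single further level applied to L3
  expect_equal(bx$levels$L4, dwt_level(bx$levels$L3)$approx, tolerance = 1e-12)
})

test_that("a single level reconstructs the input", {
  set.seed(42)
  for (n in c(19L, 57L, 250L)) {
    x <- rnorm(n)
    d <- dwt_level(x)
    expect_equal(idwt_level(d$approx, d$detail, n), x, tolerance = 1e-8)
  }
})

test_that("too-short inputs fail with the minimum length in the message", {
  expect_error(mdwt(rnorm(100), levels = 4), "need >= 199")
  expect_silent(invisible(mdwt(rnorm(199), levels = 4)))
})
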