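make_planted <- function(n, d, planted, sd_noise = 0.25, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), length.out = n))
  x <- matrix(rnorm(n * d), n, d)
  for (j in planted)
    x[, j] <- (as.integer(y) - 1.5) * 2 + rnorm(n, sd = sd_noise)
  list(x = x, y = y)
}

test_that("a planted near-label column ranks first almost always", {
  hits <- 0L
  for (s in 1:50) {
    dat <- make_planted(40, 15, planted = 7, sd_noise = 0.1, seed = s)
    r <- nca_rank(dat$x, dat$y)
    hits <- hits + (r$order[1] == 7L)
  }
  expect_gte(hits, 48L) # >= 95% recovery
})

test_that("ranking is a permutation and duplicates get near-equal weights", {
  dat <- make_planted(30, 10, planted = 3, seed = 99)
  x <- cbind(dat$x, dat$x[, 3]) # duplicate the informative column
  r <- nca_rank(x, dat$y)
  expect_setequal(r$order, seq_len(ncol(x)))
  expect_equal(r$weights[3], r$weights[11], tolerance = 1e-6)
  # objective trace is non-decreasing (ascent with rejection)
  expect_true(all(diff(r$objective) >= 0))
})

test_that("degenerate label configurations are rejected", {
  x <- matrix(rnorm(20), 4, 5)
  expect_error(nca_rank(x, factor(c("a", "a", "a", "a"))), "2 classes")
  expect_error(nca_rank(x, factor(c("a", "b", "c", "d"))),
               "single observation")
})

test_that("selection keeps only the informative prefix", {
  wins <- 0L
  for (s in 1:20) {
    dat <- make_planted(60, 10, planted = 1:3, sd_noise = 0.3, seed = 100 + s)
    sel <- inca_select(dat$x, dat$y, iv = 3, fv = 10, seed = s)
    # planted features must be selected; pure-noise padding usually is not
    expect_true(all(1:3 %in% sel$indices))
    wins <- wins + (sel$size == 3L)
  }
  expect_gt(wins, 10L) # majority outcome across seeds
})

test_that("the sweep truncates at the column count and validates iv", {
  dat <- make_planted(40, 8, planted = 1, seed = 7)
  sel <- inca_select(dat$x, dat$y, iv = 3, fv = 50, seed = 1)
  expect_identical(as.integer(names(sel$accuracy_curve)[length(sel$accuracy_curve)]),
                   8L)
  expect_error(inca_select(dat$x, dat$y, iv = 9, fv = 12, seed = 1),
               "smaller iv")
})

test_that("reported accuracy is reproducible from the returned indices", {
  dat <- make_planted(50, 30, planted = c(2, 9), seed = 17)
  sel <- inca_select(dat$x, dat$y, iv = 2, fv = 20, seed = 3)
  p <- knn_cv_predict(dat$x[, sel$indices, drop = FALSE], dat$y,
                      fold_id = sel$fold_id)
  expect_identical(prediction_accuracy(p, dat$y), sel$cv_accuracy)
  # nesting: candidate subsets are prefixes of one fixed ranking
  expect_identical(sel$indices, sel$ranking$order[seq_len(sel$size)])
  # determinism under a fixed fold seed
  sel2 <- inca_select(dat$x, dat$y, iv = 2, fv = 20, seed = 3)
  expect_identical(sel$indices, sel2$indices)
  expect_identical(sel$accuracy_curve, sel2$accuracy_curve)
})
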