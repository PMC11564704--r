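round2 <- function(x) lattice123:::round_half_up(x, 2)

test_that("worked metric identities hold at two decimals", {
  # geometric mean from the two class-wise sensitivities
  expect_equal(round2(geometric_mean(93.97, 99.60)), 96.74)
  expect_equal(round2(geometric_mean(99.75, 99.15)), 99.45)
  # F1 from precision and recall
  expect_equal(round2(f1_score(98.49, 93.97)), 96.18)
})

test_that("class-wise rates aggregate consistently (regression fixtures)", {
  # two internally consistent report rows: overall values are unweighted
  # means of the class-wise entries, GM is the sensitivity geometric mean
  rows <- list(
    list(sens = c(99.60, 93.97), prec = c(98.34, 98.49),
         f1 = c(98.97, 96.18), overall_sens = 96.79, overall_prec = 98.42,
         overall_f1 = 97.58, gm = 96.74),
    list(sens = c(99.75, 99.15), prec = c(99.75, 99.15),
         f1 = c(99.75, 99.15), overall_sens = 99.45, overall_prec = 99.45,
         overall_f1 = 99.45, gm = 99.45))
  for (r in rows) {
    expect_equal(round2(mean(r$sens)), r$overall_sens)
    expect_equal(round2(mean(r$prec)), r$overall_prec)
    expect_equal(round2(mean(r$f1)), r$overall_f1)
    expect_equal(round2(geometric_mean(r$sens[1], r$sens[2])), r$gm)
    for (k in 1:2)
      expect_equal(round2(f1_score(r$prec[k], r$sens[k])), r$f1[k],
                   tolerance = 0.011) # printed inputs are pre-rounded
  }
})

test_that("the report computes a coherent confusion matrix and rates", {
  truth <- factor(c(rep("healthy", 8), rep("AD", 4)))
  pred  <- c("healthy", "healthy", "healthy", "healthy", "healthy",
             "healthy", "AD", "AD", "AD", "AD", "AD", "healthy")
  m <- compute_metrics(pred, truth)
  expect_identical(sum(m$confusion), 12L)
  expect_identical(as.integer(m$confusion["healthy", "healthy"]), 6L)
  expect_identical(as.integer(m$confusion["AD", "AD"]), 3L)
  expect_equal(m$accuracy, 100 * 9 / 12)
  expect_equal(m$per_class["healthy", "sensitivity"], 100 * 6 / 8)
  expect_equal(m$per_class["AD", "sensitivity"], 100 * 3 / 4)
  expect_equal(m$per_class["healthy", "specificity"],
               m$per_class["AD", "sensitivity"])
  expect_equal(m$geometric_mean,
               sqrt(m$per_class[1, "sensitivity"] * m$per_class[2, "sensitivity"]))
  # macro rates are unweighted means
  expect_equal(unname(m$macro["sensitivity"]),
               mean(m$per_class$sensitivity))
})

test_that("perfect predictions score 100 everywhere", {
  truth <- factor(rep(c("healthy", "AD"), c(9, 3)))
  m <- compute_metrics(truth, truth)
  expect_equal(m$accuracy, 100)
  expect_equal(m$geometric_mean, 100)
  expect_true(all(unlist(m$per_class) == 100))
})

test_that("metric invariances: label swap and AM-GM", {
  set.seed(71)
  for (rep in 1:20) {
    truth <- factor(sample(c("x", "y"), 40, replace = TRUE,
                           prob = c(0.7, 0.3)))
    pred <- as.character(truth)
    flip <- sample(40, 8)
    pred[flip] <- ifelse(pred[flip] == "x", "y", "x")
    m <- compute_metrics(pred, truth)
    # swapping the positive-class convention changes nothing global
    relev <- function(v) factor(as.character(v), levels = c("y", "x"))
    m2 <- compute_metrics(relev(pred), relev(truth))
    expect_equal(m2$accuracy, m$accuracy)
    expect_equal(m2$geometric_mean, m$geometric_mean)
    expect_equal(unname(m2$macro), unname(m$macro))
    # GM never exceeds the macro sensitivity
    expect_lte(m$geometric_mean, unname(m$macro["sensitivity"]) + 1e-12)
  }
})

test_that("unseen predicted labels are an error", {
  truth <- factor(rep(c("a", "b"), 5))
  expect_error(compute_metrics(c(rep("a", 9), "c"), truth), "unseen")
})
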