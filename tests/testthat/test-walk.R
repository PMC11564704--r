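topo <- default_lattice()

test_that("equal probabilities give the leftmost path for both kinds", {
  p <- rep(1 / 19, 19)
  leftmost <- c(1L, 2L, 4L, 7L, 10L, 13L, 16L, 18L, 19L)
  expect_identical(as.integer(lattice_walk(topo, p, "minimum")), leftmost)
  expect_identical(as.integer(lattice_walk(topo, p, "maximum")), leftmost)
})

test_that("monotone probabilities drive the walks to opposite extremes", {
  p <- (1:19) / sum(1:19) # strictly increasing with vertex id
  wmin <- as.integer(lattice_walk(topo, p, "minimum"))
  wmax <- as.integer(lattice_walk(topo, p, "maximum"))
  # step-by-step simulation: minimum always takes the lowest-id child,
  # maximum the highest-id child
  sim <- function(pick) {
    path <- 1L
    for (t in 1:8) path <- c(path, pick(lattice_children(topo, path[t])))
    path
  }
  expect_identical(wmin, sim(min))
  expect_identical(wmax, sim(max))
})

test_that("walks always satisfy the path invariants", {
  edge_keys <- paste(topo$edges[, 1], topo$edges[, 2])
  set.seed(11)
  for (rep in 1:200) {
    p <- runif(19)
    for (kind in c("minimum", "maximum")) {
      w <- as.integer(lattice_walk(topo, p, kind))
      expect_identical(w[1], 1L)
      expect_identical(w[9], 19L)
      expect_length(w, 9L)
      expect_true(all(paste(w[-9], w[-1]) %in% edge_keys))
    }
  }
})

test_that("walk agrees with the brute-force oracle on random assignments", {
  set.seed(12)
  for (rep in 1:1000) {
    p <- runif(19)
    if (rep %% 5 == 0) p <- round(p, 1) # force ties regularly
    expect_identical(as.integer(lattice_walk(topo, p, "minimum")),
                     ref_walk(topo, p, "minimum"))
    expect_identical(as.integer(lattice_walk(topo, p, "maximum")),
                     ref_walk(topo, p, "maximum"))
  }
})

test_that("probabilities of unreachable vertices do not affect the walk", {
  set.seed(13)
  for (rep in 1:50) {
    p <- runif(19)
    w <- as.integer(lattice_walk(topo, p, "minimum"))
    # vertices never adjacent to the path are free to change
    touched <- unique(c(w, unlist(lapply(w, lattice_children, topology = topo))))
    free <- setdiff(1:19, touched)
    if (!length(free)) next
    p2 <- p
    p2[free] <- runif(length(free))
    expect_identical(as.integer(lattice_walk(topo, p2, "minimum")), w)
  }
})

test_that("missing or short probability vectors are rejected", {
  expect_error(lattice_walk(topo, rep(0.1, 18)), "one probability per vertex")
  p <- rep(0.1, 19); p[4] <- NA
  expect_error(lattice_walk(topo, p), "missing probability")
})
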