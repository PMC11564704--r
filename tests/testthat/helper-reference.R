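# Straight-line reference implementation of the lattice graph pattern
# transform: plain loops, no vectorization, no shared code with the
# production path beyond the topology's edge table. Serves as the
# independent oracle for bit-exact equivalence checks.
ref_lattice123 <- function(signal, topology) {
  n <- length(signal)
  mn <- min(signal); mx <- max(signal)
  norm <- if (mn == mx) rep(1L, n)
          else as.integer(ceiling((signal - mn) / (mx - mn) * 99)) + 1L
  pr <- numeric(100)
  for (v in 1:100) pr[v] <- sum(norm == v) / n
  tr <- sqrt(mean((signal - mean(signal))^2)) / 2
  kids <- lapply(1:topology$n_vertices, function(v)
    sort(topology$edges[topology$edges[, 1] == v, 2]))
  cat_defs <- list(c("min", "signum"), c("max", "signum"), c("min", "upper"),
                   c("min", "lower"), c("max", "upper"), c("max", "lower"))
  hist6 <- matrix(0L, 6, 256)
  for (i in 1:(n - 18)) {
    raw <- signal[i:(i + 18)]
    prob <- pr[norm[i:(i + 18)]]
    paths <- list()
    for (kind in c("min", "max")) {
      path <- 1L
      for (t in 1:8) {
        cand <- kids[[path[t]]]
        pick <- cand[1]
        for (kk in cand) {
          if (kind == "min") {
            if (prob[kk] < prob[pick]) pick <- kk
          } else {
            if (prob[kk] > prob[pick]) pick <- kk
          }
        }
        path <- c(path, pick)
      }
      paths[[kind]] <- path
    }
    for (ci in 1:6) {
      kd <- cat_defs[[ci]]
      p <- paths[[kd[1]]]
      dec <- 0L
      for (t in 1:8) {
        a <- raw[p[t]]; b <- raw[p[t + 1]]
        bit <- switch(kd[2],
                      signum = as.integer(a - b >= 0),
                      upper  = as.integer(a - b > tr),
                      lower  = as.integer(a - b < -tr))
        dec <- dec + bit * 2L^(t - 1)
      }
      hist6[ci, dec + 1] <- hist6[ci, dec + 1] + 1L
    }
  }
  hist6
}

# Brute-force greedy walk: scans the child list at each tier and applies the
# comparison directly.
ref_walk <- function(topology, prob, kind) {
  prob <- unname(prob)
  path <- 1L
  for (t in seq_len(length(topology$tiers) - 1)) {
    cand <- sort(topology$edges[topology$edges[, 1] == path[t], 2])
    best <- cand[1]
    for (v in cand) {
      if (kind == "minimum" && prob[v] < prob[best]) best <- v
      if (kind == "maximum" && prob[v] > prob[best]) best <- v
    }
    path <- c(path, best)
  }
  unname(path)
}

# Brute-force iterative hard majority vote: per-epoch label counting with
# table(), ties to the most accurate member holding a tied label.
ref_ihmv <- function(predictions, labels) {
  acc <- sapply(predictions, function(p) mean(as.character(p) == as.character(labels)))
  ord <- order(acc, decreasing = TRUE)
  np <- length(predictions)
  n <- length(labels)
  out <- list()
  for (r in 3:np) {
    members <- ord[1:r]
    voted <- character(n)
    for (e in 1:n) {
      votes <- sapply(members, function(m) as.character(predictions[[m]][e]))
      tab <- table(votes)
      modal <- names(tab)[tab == max(tab)]
      voted[e] <- votes[votes %in% modal][1] # first member in accuracy order
    }
    out[[r - 2]] <- voted
  }
  out
}

random_signal <- function(len, style = c("gauss", "integer", "spiky")) {
  style <- match.arg(style)
  switch(style,
         gauss = rnorm(len),
         integer = sample(-20:20, len, replace = TRUE),
         spiky = rnorm(len) + 10 * (runif(len) < 0.05))
}
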