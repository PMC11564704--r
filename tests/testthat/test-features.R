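test_that("channel features are six 1280-long source-blocked vectors", {
  set.seed(51)
  x <- rnorm(750)
  fs <- extract_channel_features(x)
  expect_identical(dim(fs), c(6L, 1280L))
  expect_identical(attr(fs, "sources"), c("raw", "L1", "L2", "L3", "L4"))
  # first 256 entries are the raw-signal histogram of each category
  raw_h <- lattice123(x)
  expect_identical(unname(fs[, 1:256]), unname(unclass(raw_h)))
  # each source block conserves its own block count
  bands <- mdwt(x)
  src_len <- unname(c(length(x), lengths(bands$levels)))
  for (p in 0:4) {
    block <- fs[, (p * 256 + 1):((p + 1) * 256)]
    expect_identical(as.integer(rowSums(block)), rep(src_len[p + 1] - 18L, 6L))
  }
  # slicing recovers the per-source histograms exactly
  for (p in 1:4) {
    hp <- lattice123(bands$levels[[p]])
    expect_identical(unname(fs[, (p * 256 + 1):((p + 1) * 256)]),
                     unname(unclass(hp)))
  }
})

test_that("raw-signal entries are independent of deep subband content", {
  set.seed(52)
  x <- rnorm(750)
  full <- extract_channel_features(x)
  expect_identical(unname(full[, 1:256]), unname(unclass(lattice123(x))))
})

test_that("batch extraction is organized per channel and category", {
  cfg <- synth_config(n_channels = 2L, n_epochs = c(healthy = 3L, AD = 2L),
                      epoch_length = 400L, seed = 5L)
  col <- generate_synthetic(cfg)
  feats <- extract_features(col)
  expect_length(feats, 2L)
  expect_named(feats[[1]],
               c("min_signum", "max_signum", "min_upper",
                 "min_lower", "max_upper", "max_lower"))
  expect_identical(dim(feats[[1]][[1]]), c(5L, 1280L))
  # row e of the batch equals a direct single-epoch extraction
  direct <- extract_channel_features(col$epochs[3, 2, ])
  for (k in 1:6)
    expect_identical(feats[[2]][[k]][3, ], unname(direct[k, ]))
})

test_that("feature export writes matrices plus a JSON sidecar", {
  cfg <- synth_config(n_channels = 1L, n_epochs = c(healthy = 2L, AD = 2L),
                      epoch_length = 400L, seed = 6L)
  feats <- extract_features(generate_synthetic(cfg))
  dir <- withr::local_tempdir()
  sidecar <- write_features(feats, dir)
  expect_true(file.exists(sidecar))
  meta <- jsonlite::read_json(sidecar)
  expect_equal(as.numeric(meta$vector_length), 1280)
  files <- list.files(dir, pattern = "^features_.*csv$")
  expect_length(files, 6L)
  back <- as.matrix(utils::read.csv(file.path(dir, files[1]), header = FALSE))
  expect_identical(dim(back), c(4L, 1280L))
})
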