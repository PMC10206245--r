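test_that("count_matrix validates its invariants", {
  m <- matrix(0:5, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  cm <- count_matrix(m, c("FH", "SFH"))
  expect_s3_class(cm, "count_matrix")
  expect_equal(unname(dim(cm)), c(3L, 2L))
  expect_named(cm$groups, c("s1", "s2"))

  expect_error(count_matrix(m, c("FH", "XX")), "FH")
  expect_error(count_matrix(m - 1, c("FH", "SFH")), "non-negative")
  m2 <- m; rownames(m2) <- c("a", "a", "c")
  expect_error(count_matrix(m2, c("FH", "SFH")), "duplicate")
  expect_error(count_matrix(m, c("FH")), "length")
})

test_that("counts round-trip through TSV with the sample sheet", {
  cm <- random_count_matrix(10, 3, 3, seed = 1)
  counts_path <- withr::local_tempfile(fileext = ".tsv")
  sheet_path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cm, counts_path, sheet_path)
  back <- read_counts(counts_path, sheet_path, kind = "miRNA")
  expect_identical(back$counts, cm$counts)
  expect_identical(back$groups, cm$groups)
})

test_that("drop_zero_features removes exactly the all-zero rows", {
  m <- matrix(c(1, 0, 2, 3, 0, 4), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  cm <- count_matrix(m, c("FH", "SFH"))
  out <- drop_zero_features(cm)
  expect_identical(rownames(out$counts), c("a", "c"))
  expect_identical(attr(out, "n_dropped"), 1L)

  # no all-zero rows: unchanged
  cm2 <- random_count_matrix(20, 3, 3, seed = 2)
  cm2$counts[cm2$counts == 0] <- 1L
  cm2 <- count_matrix(cm2$counts, cm2$groups)
  expect_identical(drop_zero_features(cm2)$counts, cm2$counts)

  all0 <- count_matrix(matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
                       c("FH", "SFH"))
  expect_error(drop_zero_features(all0), "zero")
})

test_that("cpm normalizes each sample to one million and keeps zeros", {
  m <- matrix(c(10, 999990, 5, 499995), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  x <- cpm(count_matrix(m, c("FH", "SFH")))
  expect_equal(x$cpm["a", "s1"], 10)
  expect_equal(x$cpm["a", "s2"], 10)

  cm <- random_count_matrix(50, 4, 4, seed = 3)
  x2 <- cpm(cm)
  expect_equal(unname(colSums(x2$cpm)), rep(1e6, 8), tolerance = 1e-9)
  expect_identical(x2$cpm == 0, cm$counts == 0)

  bad <- count_matrix(matrix(c(1L, 0L, 0L, 0L), 2, 2,
                             dimnames = list(c("a", "b"), c("s1", "s2"))),
                      c("FH", "SFH"))
  expect_error(cpm(bad), "s2")
})

test_that("prevalence filter keeps features at >= min_cpm in >= half the samples", {
  # every sample totals exactly 1e6, so CPM equals the raw count
  n <- 14
  probe_in7 <- as.integer(c(rep(1, 7), rep(0, 7)))   # CPM 1 in exactly half
  probe_never <- rep(0L, n)
  probe_never[1] <- 0L
  filler <- 1e6L - probe_in7 - probe_never
  counts <- rbind(probe_in7 = probe_in7, probe_never = probe_never,
                  filler = filler)
  colnames(counts) <- sprintf("s%02d", 1:n)
  cm <- count_matrix(counts, rep(c("FH", "SFH"), each = 7))
  kept <- rownames(prevalence_filter(cm)$counts)
  expect_true("probe_in7" %in% kept)     # boundary: exactly 50% is kept
  expect_false("probe_never" %in% kept)  # CPM >= 1 in 0 samples

  expect_error(prevalence_filter(cm, min_frac = 0), "min_frac")
  expect_error(prevalence_filter(cm, min_frac = 1.5), "min_frac")
})

test_that("prevalence filter matches a feature-by-feature loop oracle", {
  cm <- random_count_matrix(200, 7, 7, seed = 5, mu_log = 1)
  kept <- rownames(prevalence_filter(cm)$counts)
  tot <- colSums(cm$counts)
  oracle <- character(0)
  for (f in rownames(cm$counts)) {
    ok <- 0
    for (s in colnames(cm$counts)) {
      if (cm$counts[f, s] / tot[s] * 1e6 >= 1) ok <- ok + 1
    }
    if (ok / ncol(cm$counts) >= 0.5) oracle <- c(oracle, f)
  }
  expect_identical(kept, oracle)
})

test_that("prevalence filter is idempotent under fixed library sizes", {
  cm <- random_count_matrix(100, 7, 7, seed = 6, mu_log = 1)
  tot <- colSums(cm$counts)
  once <- prevalence_filter(cm, lib_sizes = tot)
  twice <- prevalence_filter(once, lib_sizes = tot)
  expect_identical(once$counts, twice$counts)
})
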