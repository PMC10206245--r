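test_that("correlation_matrix matches the textbook formula", {
  set.seed(13)
  x <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("f%02d", 1:20), sprintf("s%d", 1:6)))
  r <- correlation_matrix(x)
  # duplicate and negated features
  x2 <- rbind(x, dup = x[1, ], neg = -x[2, ])
  r2 <- correlation_matrix(x2)
  expect_equal(r2["f01", "dup"], 1)
  expect_equal(r2["f02", "neg"], -1)
  expect_equal(unname(diag(r)), rep(1, 20))

  # two-pass formula oracle
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    xi <- x[i, ] - mean(x[i, ]); xj <- x[j, ] - mean(x[j, ])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_lt(max(abs(r - oracle)), 1e-12)

  # zero-variance feature gets r = 0 and a warning
  x3 <- rbind(x[1:3, ], flat = rep(2, 6))
  expect_warning(r3 <- correlation_matrix(x3), "zero-variance")
  expect_equal(unname(r3["flat", 1:3]), rep(0, 3))
  expect_equal(r3["flat", "flat"], 1)

  expect_error(correlation_matrix(x[, 1:2]), ">= 3 samples")
})

test_that("the PCIT trio formula reproduces the worked example", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- 0.8
  r[2, 3] <- r[3, 2] <- 0.7
  expect_equal(partial_correlation(0.9, 0.8, 0.7), 0.34 / sqrt(0.36 * 0.51),
               tolerance = 1e-12)
  sig <- pcit(r)
  expect_true(is.logical(sig))
})

test_that("an isolated correlated pair is never eliminated", {
  r <- diag(5)
  r[1, 2] <- r[2, 1] <- 0.8
  sig <- pcit(r)
  expect_true(sig[1, 2])
})

test_that("pcit matches the exhaustive triple-loop oracle", {
  for (seed in 1:10) {
    r <- random_corr(15, 8, seed)
    got <- pcit(r)
    expect_identical(unname(got[, ]), pcit_bruteforce(r),
                     label = sprintf("seed %d", seed))
  }
})

test_that("pcit is permutation-equivariant and symmetric", {
  r <- random_corr(12, 6, 99)
  sig <- pcit(r)
  expect_identical(sig, t(sig))
  perm <- sample(12)
  sig_p <- pcit(r[perm, perm])
  expect_identical(unname(sig_p[, ]), unname(sig[perm, perm]))
})

test_that("trios with a perfect pairwise correlation are skipped", {
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 1       # duplicated feature
  r[1, 3] <- r[3, 1] <- 0.5
  r[2, 3] <- r[3, 2] <- 0.5
  r[1, 4] <- r[4, 1] <- -0.2
  r[2, 4] <- r[4, 2] <- -0.2
  r[3, 4] <- r[4, 3] <- 0.1
  sig <- pcit(r)
  # the two trios containing the perfect pair are skipped
  expect_identical(attr(sig, "skipped_trios"), 2)
})

test_that("group networks keep only strong miRNA-involving PCIT edges", {
  set.seed(14)
  # construct CPM-like profiles with one engineered miRNA-gene pair
  n <- 6
  samples <- c(sprintf("FH%d", 1:3), sprintf("SFH%d", 1:3))
  groups <- setNames(rep(c("FH", "SFH"), each = 3), samples)
  base <- abs(matrix(rnorm(5 * n, 100, 30), 5, n))
  mi <- rbind(mir1 = c(10, 50, 90, 10, 50, 90),
              mir2 = abs(rnorm(n, 50, 20)))
  colnames(mi) <- samples
  g <- rbind(geneA = c(90, 50, 10, 90, 50, 10),  # anti-tracks mir1
             geneB = abs(rnorm(n, 80, 5)))
  colnames(g) <- samples
  cpm_mi <- structure(list(cpm = mi, groups = factor(groups, c("FH", "SFH")),
                           kind = "miRNA", lib_sizes = rep(1e6, n)),
                      class = "cpm_matrix")
  cpm_g <- structure(list(cpm = g, groups = factor(groups, c("FH", "SFH")),
                          kind = "gene", lib_sizes = rep(1e6, n)),
                     class = "cpm_matrix")
  net <- build_group_network(cpm_mi, cpm_g, demis = c("mir1", "mir2"),
                             target_genes = c("geneA", "geneB"), group = "FH")
  expect_true(all(net$edges$edge_class != "gene-gene"))
  expect_true(all(abs(net$edges$r) > 0.6))
  expect_true(all(net$edges$pcit_significant))
  key <- paste(net$edges$node_a, net$edges$node_b)
  expect_true("geneA mir1" %in% key)
  # gene-gene pairs are present in the full dump
  expect_true(any(net$all_pairs$edge_class == "gene-gene"))
  # raising r_min never adds edges
  net2 <- build_group_network(cpm_mi, cpm_g, demis = c("mir1", "mir2"),
                              target_genes = c("geneA", "geneB"),
                              group = "FH", r_min = 0.9)
  expect_true(all(paste(net2$edges$node_a, net2$edges$node_b) %in% key))
  expect_lte(nrow(net2$edges), nrow(net$edges))
})
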