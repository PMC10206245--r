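test_that("the embedded energy table loads and is nearest-neighbor symmetric", {
  p <- duplex_params()
  expect_identical(dim(p$stack), c(6L, 6L))
  rev_pair <- function(x) paste0(substr(x, 2, 2), substr(x, 1, 1))
  for (p1 in rownames(p$stack)) for (p2 in colnames(p$stack)) {
    expect_equal(p$stack[p1, p2], p$stack[rev_pair(p2), rev_pair(p1)],
                 tolerance = 1e-12)
  }
  expect_gt(p$init, 0)
  expect_true(all(p$bulge > 0))
  # internal loops start at total length 2; index 1 is an unused placeholder
  expect_identical(p$internal[1], 0)
  expect_true(all(p$internal[-1] > 0))
})

test_that("perfect-complement duplex energy equals the hand-summed stacks", {
  set.seed(15)
  for (len in c(10, 14, 21)) {
    mi <- random_rna_str(len)
    target <- rc_oracle(mi)
    d <- duplex_mfe(mi, target)
    expect_equal(d$mfe, unname(stack_sum_oracle(mi)), tolerance = 1e-9,
                 label = sprintf("length %d", len))
    expect_identical(d$best_site_start, 1L)
  }
})

test_that("sequences that cannot pair return zero", {
  expect_identical(duplex_mfe("AAAAAAAAAA", "AAAAAAAAAA")$mfe, 0)
  expect_identical(duplex_mfe("CCCCCCCCCC", "AAAAAAAAAA")$mfe, 0)
})

test_that("mfe is invariant to T/U substitution", {
  set.seed(16)
  mi <- random_rna_str(21)
  target <- paste0(random_rna_str(50), rc_oracle(substr(mi, 3, 15)),
                   random_rna_str(50))
  a <- duplex_mfe(mi, target)
  b <- duplex_mfe(chartr("U", "T", mi), chartr("U", "T", target))
  expect_identical(a, b)
})

test_that("appending complementary nucleotides never weakens the duplex", {
  set.seed(17)
  for (i in 1:10) {
    mi <- random_rna_str(12)
    target <- rc_oracle(mi)
    base <- duplex_mfe(mi, target)$mfe
    ext <- random_rna_str(4)
    mi2 <- paste0(mi, ext)            # extend miRNA 3' end
    target2 <- paste0(rc_oracle(ext), target)  # complementary target 5' end
    expect_lte(duplex_mfe(mi2, target2)$mfe, base)
  }
})

test_that("perfect complements at miRNA length clear the -20 kcal/mol cutoff", {
  # at mature-miRNA length (21-22 nt) a full-length duplex is always below
  # the affinity cutoff; at 14 nt AU-rich sequences can fall short of it
  # (weakest stack -0.9 kcal/mol), so only the typical case is asserted
  set.seed(18)
  for (i in 1:20) {
    mi <- random_rna_str(sample(21:22, 1))
    expect_lt(duplex_mfe(mi, rc_oracle(mi))$mfe, -20)
  }
  v14 <- vapply(1:40, function(i) {
    mi <- random_rna_str(14)
    duplex_mfe(mi, rc_oracle(mi))$mfe
  }, 0.0)
  expect_gte(mean(v14 < -20), 0.75)
})

test_that("interior mismatches cost loop penalties but keep the best site", {
  mi <- "GGGGGCCCCCGGGGG"
  target <- rc_oracle(mi)
  clean <- duplex_mfe(mi, target)$mfe
  # break the middle of the target: DP must bridge with an internal loop
  broken <- paste0(substr(target, 1, 6), "AAA", substr(target, 10, 15))
  d <- duplex_mfe(mi, broken)
  expect_gt(d$mfe, clean)  # less favorable than the perfect duplex
  expect_lt(d$mfe, 0)      # but still stable
})

test_that("per-gene averages use the arithmetic mean and a strict cutoff", {
  recs <- data.frame(mirna_id = "m1",
                     gene_id = c("gA", "gB", "gB", "gC", "gC", "gC"),
                     mfe = c(-30, -25, -15, -30, -21, -24))
  out <- gene_average_mfe(recs)
  expect_equal(out$gene_avg_mfe[out$gene_id == "gA"], -30)   # single transcript
  expect_equal(out$gene_avg_mfe[out$gene_id == "gB"], -20)
  expect_false(out$passes_cutoff[out$gene_id == "gB"])       # strict < -20
  expect_equal(out$gene_avg_mfe[out$gene_id == "gC"], -25)
  expect_true(out$passes_cutoff[out$gene_id == "gC"])
  expect_identical(out$n_transcripts, c(1L, 2L, 3L))
})

test_that("duplex_mfe_set maps transcripts to genes", {
  mirnas <- c(m1 = "ACGUACGUACGUACGUACGU")
  txs <- c("gA.t1" = rc_oracle(mirnas[["m1"]]),
           "gA.t2" = random_rna_str(40))
  set.seed(19)
  recs <- duplex_mfe_set(mirnas, txs)
  expect_identical(recs$gene_id, c("gA", "gA"))
  avg <- gene_average_mfe(recs)
  expect_identical(nrow(avg), 1L)
  expect_equal(avg$gene_avg_mfe, mean(recs$mfe))
})
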