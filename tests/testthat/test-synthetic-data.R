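small_cfg <- function(seed = 1, frac_de = 6 / 60, ...) {
  synthetic_config(n_mirna = 60, n_gene = 120, frac_de_mirna = frac_de,
                   n_target_genes = 6, n_decoy_utr = 8,
                   utr_len_range = c(300, 600), seed = seed, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  a <- synthetic_dataset(small_cfg(seed = 7))
  b <- synthetic_dataset(small_cfg(seed = 7))
  expect_identical(a$mirna$counts, b$mirna$counts)
  expect_identical(a$mrna$counts, b$mrna$counts)
  expect_identical(a$mirna_seqs, b$mirna_seqs)
  expect_identical(a$utr_seqs, b$utr_seqs)
  expect_identical(a$pathways, b$pathways)
  expect_identical(a$truth$target_pairs, b$truth$target_pairs)
  c <- synthetic_counts(small_cfg(seed = 8))
  expect_false(identical(a$mirna$counts, c$mirna$counts))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(coupling_slope = 0), "coupling_slope")
  expect_error(synthetic_config(coupling_slope = -1), "coupling_slope")
  expect_error(synthetic_config(de_log2fc_range = c(0.2, 2)), "0.5")
  expect_error(synthetic_config(n_fh_mirna = 0), "positive")
  expect_error(synthetic_config(rewired_fraction = 1.2), "rewired_fraction")
})

test_that("frac_de_mirna = 0 plants no fold changes", {
  out <- synthetic_counts(small_cfg(frac_de = 0))
  expect_identical(nrow(out$truth$de_mirnas), 0L)
  expect_identical(nrow(out$truth$target_pairs), 0L)
})

test_that("counts are NB over-dispersed: variance exceeds the mean", {
  out <- synthetic_counts(synthetic_config(n_mirna = 1000, n_gene = 10,
                                           frac_de_mirna = 0, seed = 3))
  counts <- out$mirna$counts
  v <- apply(counts, 1, var)
  m <- rowMeans(counts)
  keep <- m > 5
  expect_gt(mean(v[keep] > m[keep]), 0.9)
})

test_that("planted pairs correlate negatively only in their active group", {
  # aggregate planted pairs over several seeds for a stable count
  act_r <- c(); inact_r <- c()
  for (seed in 1:12) {
    out <- synthetic_counts(small_cfg(seed = seed, rewired_fraction = 1))
    mi_cpm <- cpm(out$mirna)$cpm
    g_cpm <- cpm(out$mrna)$cpm
    tp <- out$truth$target_pairs
    for (i in seq_len(nrow(tp))) {
      act <- tp$active_group[i]
      inact <- setdiff(c("FH", "SFH"), act)
      s_act <- intersect(colnames(mi_cpm)[startsWith(colnames(mi_cpm), act)],
                         colnames(g_cpm))
      s_in <- intersect(colnames(mi_cpm)[startsWith(colnames(mi_cpm), inact)],
                        colnames(g_cpm))
      act_r <- c(act_r, cor(mi_cpm[tp$mirna_id[i], s_act],
                            g_cpm[tp$gene_id[i], s_act]))
      inact_r <- c(inact_r, cor(mi_cpm[tp$mirna_id[i], s_in],
                                g_cpm[tp$gene_id[i], s_in]))
    }
  }
  expect_gte(mean(act_r < -0.6), 0.9)     # coupling shows where active
  # confinement: in the inactive group the pair is independent, so |r|
  # follows the null distribution at n = 6-7 samples, where
  # P(|r| < 0.6) ~ 0.8; the planted coupling must not leak beyond that
  expect_gte(mean(abs(inact_r) < 0.6), 0.75)
  expect_lt(mean(inact_r), 0.15)          # no systematic coupling leak
  expect_gt(mean(inact_r) - mean(act_r), 0.5)
})

test_that("planted seed sites are written at the recorded class and position", {
  dat <- synthetic_dataset(small_cfg(seed = 5))
  ps <- dat$truth$planted_sites
  expect_gt(nrow(ps), 0)
  for (i in seq_len(nrow(ps))) {
    hits <- scan_seed_sites(dat$mirna_seqs[[ps$mirna_id[i]]],
                            dat$utr_seqs[[ps$transcript_id[i]]])
    j <- which(hits$utr_start == ps$utr_start[i])
    expect_length(j, 1)
    expect_identical(as.character(hits$site_type[j]),
                     as.character(ps$site_type[i]))
  }
})

test_that("decoy UTRs carry no site for any planted miRNA", {
  dat <- synthetic_dataset(small_cfg(seed = 6))
  planted_mirnas <- unique(dat$truth$target_pairs$mirna_id)
  decoy_tx <- setdiff(names(dat$utr_seqs),
                      dat$truth$planted_sites$transcript_id)
  expect_gt(length(decoy_tx), 0)
  for (tid in decoy_tx) {
    for (mid in planted_mirnas) {
      expect_identical(nrow(scan_seed_sites(dat$mirna_seqs[[mid]],
                                            dat$utr_seqs[[tid]])), 0L,
                       label = sprintf("%s vs %s", mid, tid))
    }
  }
})

test_that("the planted pathway term is strongly over-represented", {
  # at the default scale (741-gene universe, 16 planted targets)
  cnt <- synthetic_counts(synthetic_config(seed = 9))
  pw <- synthetic_pathways(cnt$truth)
  truth <- pw$truth
  expect_identical(truth$enriched_term, "SYNPATH_PLANTED")
  targets <- unique(truth$target_pairs$gene_id)
  overlap <- length(intersect(pw$sets[[truth$enriched_term]], targets))
  expect_identical(overlap, truth$enriched_overlap)
  p <- hypergeom_test(targets, pw$sets[[truth$enriched_term]],
                      truth$gene_ids)
  expect_lt(p, 1e-6)
  # decoy terms are uniform draws from the universe
  expect_gte(length(pw$sets), 21L)

  # reference configuration: a 15-gene term with 10 members among 40
  # query genes in a 741-gene universe is far beyond 1e-6
  expect_lt(hyper_tail_oracle(10, 15, 741, 40), 1e-6)
})

test_that("pathway generation flags an empty truth", {
  out <- synthetic_counts(small_cfg(frac_de = 0))
  expect_warning(pw <- synthetic_pathways(out$truth), "no planted target")
  expect_null(pw$enriched_term)
  expect_error(synthetic_pathways(out$truth, term_size = 1e5), "universe")
})

test_that("FASTA output round-trips through the reader", {
  dat <- synthetic_dataset(small_cfg(seed = 10))
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(dat$mirna_seqs, path, comment = "test")
  back <- read_fasta(path)
  expect_identical(back, dat$mirna_seqs)
})
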