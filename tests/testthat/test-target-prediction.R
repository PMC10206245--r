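# miRNA with positions 1-8 = UAAGGCAC: seed (2-7) = AAGGCA, whose target
# match is UGCCUU; m8 complement of C is G; so GUGCCUUA is a full 8mer site.
MIR8 <- "UAAGGCACGGUUCAAGUCUAG"

test_that("constructed sites are classified exactly", {
  hit <- scan_seed_sites(MIR8, "CCCGUGCCUUACCC")
  expect_identical(nrow(hit), 1L)
  expect_identical(as.character(hit$site_type), "8mer")
  expect_identical(hit$utr_start, 4L)
  expect_identical(hit$utr_end, 11L)

  # terminal A -> G: 7mer-m8 at the same locus
  hit2 <- scan_seed_sites(MIR8, "CCCGUGCCUUGCCC")
  expect_identical(as.character(hit2$site_type), "7mer-m8")
  expect_identical(hit2$utr_start, 4L)

  # no m8 match but site followed by A: 7mer-A1
  hit3 <- scan_seed_sites(MIR8, "CCCUUGCCUUACCC")
  expect_identical(as.character(hit3$site_type), "7mer-A1")
  expect_identical(hit3$utr_start, 5L)

  # bare seed match: 6mer
  hit4 <- scan_seed_sites(MIR8, "CCCUUGCCUUGCCC")
  expect_identical(as.character(hit4$site_type), "6mer")

  # T treated as U, lowercase accepted
  hit5 <- scan_seed_sites(tolower(chartr("U", "T", MIR8)), "cccgtgccttaccc")
  expect_identical(as.character(hit5$site_type), "8mer")

  expect_error(scan_seed_sites("UAAGGCXC", "ACGU"), "X")
  expect_error(scan_seed_sites("UAAGGCA", "ACGU"), ">= 8")
})

test_that("overlapping seed matches are each reported", {
  # seed match UGCCUU twice, overlapping arrangement via tandem repeat
  utr <- paste0("AA", "UGCCUU", "UGCCUU", "AA")
  hits <- scan_seed_sites(MIR8, utr)
  expect_identical(sort(hits$utr_start), c(3L, 9L))
})

test_that("scanner agrees with the sliding-window oracle on random UTRs", {
  set.seed(11)
  mirnas <- replicate(3, random_rna_str(22))
  for (i in 1:60) {
    utr <- random_rna_str(300)
    for (mi in mirnas) {
      got <- scan_seed_sites(mi, utr)
      want <- scan_oracle(mi, utr)
      got <- got[order(got$utr_start), ]
      want <- want[order(want$utr_start), ]
      expect_identical(as.character(got$site_type), as.character(want$site_type))
      expect_identical(got$utr_start, want$utr_start)
      expect_identical(got$utr_end, want$utr_end)
    }
  }
})

test_that("reverse-complementing the UTR mirrors seed-match loci", {
  # the seed-match locus [p, p+5] of miRNA M in a UTR maps to locus
  # n - p - 4 of the mirror miRNA M2 (seed = revcomp of M's seed) in the
  # reverse-complemented UTR
  set.seed(12)
  seed_locus <- function(hits) {
    ifelse(hits$site_type %in% c("8mer", "7mer-m8"),
           hits$utr_start + 1L, hits$utr_start)
  }
  for (i in 1:20) {
    mi <- random_rna_str(21)
    m2 <- paste0("A", rc_oracle(substr(mi, 2, 7)), random_rna_str(14))
    utr <- random_rna_str(400)
    n <- nchar(utr)
    fw <- scan_seed_sites(mi, utr)
    rv <- scan_seed_sites(m2, rc_oracle(utr))
    expect_setequal(n - seed_locus(fw) - 4L, seed_locus(rv))
  }
})

test_that("TargetScan tables filter on the score threshold inclusively", {
  tab <- data.frame(miRNA = sprintf("m%02d", 1:6),
                    gene = sprintf("g%02d", 1:6),
                    context_score = c(-0.41, -0.39, -0.4, 0.1, -1.2, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(pred <- load_targetscan(path), "unparseable")
  expect_setequal(pred$mirna_id, c("m01", "m03", "m05"))  # -0.41, -0.4, -1.2

  empty <- tab[0, ]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(empty, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(nrow(load_targetscan(path2)), 0L)

  bad <- data.frame(x = 1)
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_targetscan(path3), "missing column")
})

test_that("intersecting with expressed genes has set semantics", {
  pred <- data.frame(mirna_id = c("m1", "m1", "m2"),
                     gene_id = c("g1", "g2", "g1"))
  expect_identical(nrow(intersect_expressed(pred, character(0))), 0L)
  all_in <- intersect_expressed(pred, c("g1", "g2"))
  expect_identical(nrow(all_in), 3L)
  some <- intersect_expressed(pred, "g2")
  expect_identical(some$gene_id, "g2")
})
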