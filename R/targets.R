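# Canonical seed-site scanning and TargetScan table ingestion.
#
# Site classes follow the canonical-site convention: the seed is miRNA
# nucleotides 2-7 (5'->3'); a site is the reverse complement of the seed in
# the UTR, optionally extended by a Watson-Crick match to miRNA nucleotide
# 8 (on the 5' side of the site, "m8") and/or an adenine opposite miRNA
# nucleotide 1 (on the 3' side, "A1"). G:U wobble is not accepted.

SITE_CLASSES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

# uppercase, DNA->RNA, validate alphabet
normalize_rna <- function(seq, what = "sequence") {
  s <- chartr("acgut", "ACGUU", seq)
  s <- chartr("T", "U", s)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "U"))
  if (length(bad))
    abort("%s contains non-nucleotide characters: %s", what,
          paste(bad, collapse = ", "))
  s
}

rna_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

#' Scan a UTR for canonical miRNA seed sites
#'
#' Finds all 8mer, 7mer-m8, 7mer-A1 and 6mer sites for one miRNA in one
#' UTR. Overlapping sites are all reported, but each seed-match locus is
#' reported once under its best class (8mer > 7mer-m8 > 7mer-A1 > 6mer).
#' Coordinates are 1-based inclusive on the given UTR strand, `utr_start`
#' being the site's 5'-most target nucleotide.
#'
#' @param mirna_seq Mature miRNA sequence, 5'->3', length >= 8 (RNA; T is
#'   accepted and treated as U).
#' @param utr_seq Target UTR (or cDNA) sequence, 5'->3' (DNA or RNA).
#' @return `data.frame` with columns `site_type`, `utr_start`, `utr_end`.
#' @examples
#' scan_seed_sites("UAAGGCACGG", "CCGUGCCUUACC")  # one 8mer
#' @export
scan_seed_sites <- function(mirna_seq, utr_seq) {
  mi <- normalize_rna(mirna_seq, "miRNA sequence")
  if (nchar(mi) < 8) abort("miRNA must be >= 8 nt, got %d", nchar(mi))
  utr <- normalize_rna(utr_seq, "UTR sequence")
  if (nchar(utr) == 0) abort("UTR sequence is empty")

  seed_match <- rna_revcomp(substr(mi, 2, 7))            # 6 nt
  m8_base <- chartr("ACGU", "UGCA", substr(mi, 8, 8))    # complement of nt 8

  hits <- gregexpr(seed_match, utr, fixed = TRUE)[[1]]
  if (hits[1] == -1)
    return(data.frame(site_type = character(), utr_start = integer(),
                      utr_end = integer()))
  # gregexpr skips overlapping matches of a repeat; rescan from each hit + 1
  pos <- integer(0)
  p <- 1L
  repeat {
    i <- regexpr(seed_match, substr(utr, p, nchar(utr)), fixed = TRUE)
    if (i == -1) break
    pos <- c(pos, p + as.integer(i) - 1L)
    p <- p + as.integer(i)
  }

  n <- nchar(utr)
  out <- lapply(pos, function(p) {
    has_m8 <- p >= 2 && substr(utr, p - 1, p - 1) == m8_base
    has_a1 <- p + 6 <= n && substr(utr, p + 6, p + 6) == "A"
    if (has_m8 && has_a1)
      data.frame(site_type = "8mer", utr_start = p - 1L, utr_end = p + 6L)
    else if (has_m8)
      data.frame(site_type = "7mer-m8", utr_start = p - 1L, utr_end = p + 5L)
    else if (has_a1)
      data.frame(site_type = "7mer-A1", utr_start = p, utr_end = p + 6L)
    else
      data.frame(site_type = "6mer", utr_start = p, utr_end = p + 5L)
  })
  out <- do.call(rbind, out)
  out$site_type <- factor(out$site_type, levels = SITE_CLASSES)
  out
}

#' Scan many miRNAs against many UTRs
#'
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param utrs Named character vector of UTR/cDNA sequences (names are
#'   transcript ids).
#' @return `data.frame` with columns `mirna_id`, `transcript_id`,
#'   `site_type`, `utr_start`, `utr_end` (zero rows if no hits).
#' @export
scan_target_sites <- function(mirnas, utrs) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(utrs)))
  res <- list()
  for (mid in names(mirnas)) {
    for (tid in names(utrs)) {
      h <- scan_seed_sites(mirnas[[mid]], utrs[[tid]])
      if (nrow(h))
        res[[length(res) + 1L]] <-
          cbind(data.frame(mirna_id = mid, transcript_id = tid), h)
    }
  }
  if (!length(res))
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      site_type = factor(character(), levels = SITE_CLASSES),
                      utr_start = integer(), utr_end = integer()))
  do.call(rbind, res)
}

#' Load a TargetScan-style prediction table
#'
#' Reads a TSV of miRNA-gene predictions with cumulative weighted
#' context++ scores and keeps high-confidence rows (score <= threshold;
#' more negative = stronger predicted repression).
#'
#' @param path TSV path.
#' @param score_threshold Retain rows with score <= this (default -0.4).
#' @param mirna_col,gene_col,score_col Column names in the table.
#' @return `data.frame` with columns `mirna_id`, `gene_id`,
#'   `cumulative_context_score`, filtered and ordered by (miRNA, gene).
#'   Rows with unparseable scores are skipped with a warning.
#' @export
load_targetscan <- function(path, score_threshold = -0.4,
                            mirna_col = "miRNA", gene_col = "gene",
                            score_col = "context_score") {
  tab <- read.delim(path, check.names = FALSE)
  miss <- setdiff(c(mirna_col, gene_col, score_col), names(tab))
  if (length(miss))
    abort("TargetScan table is missing column(s): %s", paste(miss, collapse = ", "))
  score <- suppressWarnings(as.numeric(tab[[score_col]]))
  if (anyNA(score)) {
    warning(sprintf("skipped %d row(s) with unparseable scores", sum(is.na(score))))
  }
  keep <- !is.na(score) & score <= score_threshold
  out <- data.frame(mirna_id = as.character(tab[[mirna_col]])[keep],
                    gene_id = as.character(tab[[gene_col]])[keep],
                    cumulative_context_score = score[keep])
  out[order(out$mirna_id, out$gene_id), , drop = FALSE]
}

#' Restrict predictions to expressed genes
#'
#' Intersects a prediction table with the set of genes passing expression
#' QC (the "expressed TargetScan genes" of the pipeline).
#'
#' @param predictions `data.frame` with at least a `gene_id` column.
#' @param expressed_genes Character vector of expressed gene ids.
#' @return The subset of `predictions` whose `gene_id` is expressed,
#'   de-duplicated and ordered by (miRNA, gene).
#' @export
intersect_expressed <- function(predictions, expressed_genes) {
  stopifnot("gene_id" %in% names(predictions))
  out <- predictions[predictions$gene_id %in% expressed_genes, , drop = FALSE]
  if ("mirna_id" %in% names(out)) {
    out <- out[!duplicated(out[c("mirna_id", "gene_id")]), , drop = FALSE]
    out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
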