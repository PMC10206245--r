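# miRNA:mRNA duplex minimum free energy.
#
# Intermolecular-only nearest-neighbor dynamic program over base pairs
# between the miRNA and an antiparallel target window: no intramolecular
# structure, Watson-Crick and G:U pairs, Turner-style stack energies with
# length-dependent bulge/internal-loop penalties and one duplex initiation
# penalty. More negative mfe = higher predicted binding affinity; the
# study's affinity cutoff is a per-gene average mfe strictly below
# -20 kcal/mol.

PAIR_ORDER <- c("AU", "UA", "CG", "GC", "GU", "UG")

.pkg_cache <- new.env(parent = emptyenv())

#' Load the embedded duplex energy parameters
#'
#' Parses the plain-text nearest-neighbor parameter table shipped with the
#' package (`extdata/duplex_energy_params.txt`) and asserts its
#' nearest-neighbor symmetry: `E(p1, p2) = E(rev p2, rev p1)` where
#' `rev(XY) = YX` (reading the stack from the other strand).
#'
#' @param path Path to a parameter file; default the shipped table.
#' @return List with `stack` (6x6 matrix, kcal/mol, pairs as
#'   query-base/target-base), `bulge`, `internal` (length-indexed
#'   penalties), `init`, `asym_slope`, `asym_max`, `maxloop`.
#' @export
duplex_params <- function(path = system.file("extdata", "duplex_energy_params.txt",
                                             package = "mirewire")) {
  cached <- .pkg_cache[[path]]
  if (!is.null(cached)) return(cached)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  tok <- strsplit(trimws(lines), "\\s+")
  kind <- vapply(tok, `[`, "", 1)
  scalar <- function(k) as.numeric(tok[[which(kind == k)]][2])

  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_ORDER, PAIR_ORDER))
  for (t in tok[kind == "stack"])
    stack[t[2], t[3]] <- as.numeric(t[4])
  if (anyNA(stack)) abort("incomplete stack table in %s", path)

  rev_pair <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (p1 in PAIR_ORDER) for (p2 in PAIR_ORDER) {
    if (abs(stack[p1, p2] - stack[rev_pair(p2), rev_pair(p1)]) > 1e-9)
      abort("stack table violates nearest-neighbor symmetry at %s/%s", p1, p2)
  }

  lenvec <- function(k) {
    rows <- tok[kind == k]
    v <- numeric(max(vapply(rows, function(t) as.integer(t[2]), 0L)))
    for (t in rows) v[as.integer(t[2])] <- as.numeric(t[3])
    v
  }
  params <- list(stack = stack, bulge = lenvec("bulge"),
                 internal = lenvec("internal"), init = scalar("init"),
                 asym_slope = scalar("asym_slope"),
                 asym_max = scalar("asym_max"),
                 maxloop = as.integer(scalar("maxloop")))
  .pkg_cache[[path]] <- params
  params
}

encode_rna <- function(s) {
  match(strsplit(s, "")[[1]], c("A", "C", "G", "U")) - 1L
}

pairtype_matrix <- function() {
  bases <- c("A", "C", "G", "U")
  pt <- matrix(-1L, 4, 4, dimnames = list(bases, bases))
  for (i in seq_along(PAIR_ORDER)) {
    p <- PAIR_ORDER[i]
    pt[substr(p, 1, 1), substr(p, 2, 2)] <- i - 1L
  }
  pt
}

#' Duplex minimum free energy of a miRNA against a target sequence
#'
#' Scans every target position for the best intermolecular duplex and
#' returns its free energy (kcal/mol, <= 0; exactly 0 when no stable
#' duplex exists) and the 1-based target position of the duplex's 5'-most
#' paired nucleotide.
#'
#' @param mirna_seq miRNA sequence, 5'->3' (RNA; T accepted as U).
#' @param target_seq Target (cDNA or UTR) sequence, 5'->3'.
#' @param params Energy parameters from [duplex_params()].
#' @return List with `mfe` and `best_site_start` (`NA` when mfe = 0).
#' @examples
#' duplex_mfe("ACGUACGUACGUACGUACGUA", "UACGUACGUACGUACGUACGU")
#' @export
duplex_mfe <- function(mirna_seq, target_seq, params = duplex_params()) {
  mi <- normalize_rna(mirna_seq, "miRNA sequence")
  ta <- normalize_rna(target_seq, "target sequence")
  if (!nchar(mi) || !nchar(ta)) abort("sequences must be non-empty")
  res <- .duplex_core(encode_rna(mi), encode_rna(ta), pairtype_matrix(),
                      params$stack, params$bulge, params$internal,
                      params$asym_slope, params$asym_max, params$init,
                      params$maxloop)
  list(mfe = res$mfe, best_site_start = res$best_site_start)
}

#' Duplex mfe for a set of miRNA-transcript pairs
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @param pairs Optional `data.frame` (`mirna_id`, `transcript_id`)
#'   restricting which duplexes to compute; default all combinations.
#' @param tx2gene Optional named character vector mapping transcript id to
#'   gene id (default: the transcript id up to the last `"."`).
#' @param params Energy parameters.
#' @return `data.frame` with `mirna_id`, `transcript_id`, `gene_id`,
#'   `mfe`, `best_site_start`.
#' @export
duplex_mfe_set <- function(mirnas, transcripts, pairs = NULL, tx2gene = NULL,
                           params = duplex_params()) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  if (is.null(pairs))
    pairs <- expand.grid(mirna_id = names(mirnas),
                         transcript_id = names(transcripts),
                         stringsAsFactors = FALSE)
  gene_of <- function(tx) {
    if (!is.null(tx2gene)) unname(tx2gene[tx]) else sub("\\.[^.]*$", "", tx)
  }
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    mid <- pairs$mirna_id[i]; tid <- pairs$transcript_id[i]
    d <- duplex_mfe(mirnas[[mid]], transcripts[[tid]], params)
    res[[i]] <- data.frame(mirna_id = mid, transcript_id = tid,
                           gene_id = gene_of(tid), mfe = d$mfe,
                           best_site_start = d$best_site_start %||% NA_integer_)
  }
  do.call(rbind, res)
}

#' Per-gene average duplex mfe and affinity cutoff
#'
#' Averages the per-transcript mfe of each miRNA-gene pair (genes with
#' multiple transcripts get the arithmetic mean) and flags pairs whose
#' average is strictly below the cutoff.
#'
#' @param records `data.frame` with columns `mirna_id`, `gene_id`, `mfe`
#'   (one row per transcript), e.g. from [duplex_mfe_set()].
#' @param mfe_cutoff Affinity cutoff in kcal/mol (default -20; a pair
#'   passes iff `gene_avg_mfe < mfe_cutoff`, strict).
#' @return `data.frame` with `mirna_id`, `gene_id`, `n_transcripts`,
#'   `gene_avg_mfe`, `passes_cutoff`.
#' @export
gene_average_mfe <- function(records, mfe_cutoff = -20) {
  stopifnot(all(c("mirna_id", "gene_id", "mfe") %in% names(records)))
  if (!nrow(records))
    return(data.frame(mirna_id = character(), gene_id = character(),
                      n_transcripts = integer(), gene_avg_mfe = numeric(),
                      passes_cutoff = logical()))
  key <- interaction(records$mirna_id, records$gene_id, drop = TRUE)
  agg <- aggregate(records$mfe, by = list(key = key), FUN = mean)
  cnt <- as.integer(table(key)[as.character(agg$key)])
  first <- records[!duplicated(key), c("mirna_id", "gene_id")]
  first <- first[match(as.character(agg$key),
                       as.character(interaction(first$mirna_id, first$gene_id,
                                                drop = TRUE))), ]
  out <- data.frame(mirna_id = first$mirna_id, gene_id = first$gene_id,
                    n_transcripts = cnt, gene_avg_mfe = agg$x,
                    passes_cutoff = agg$x < mfe_cutoff)
  out <- out[order(out$mirna_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}
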