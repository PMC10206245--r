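# Synthetic two-group dataset generator with planted ground truth.
#
# Emulates the study design: 7 FH vs 7 SFH small-RNA libraries and 7 FH vs
# 6 SFH mRNA libraries, negative-binomial counts with log-normal library
# sizes, a minority of miRNAs with planted log2 fold changes, planted
# miRNA->target pairs negatively coupled through a shared per-sample
# latent (optionally in only one group: rewiring), toy UTRs carrying
# planted canonical seed sites, and one pathway enriched in the planted
# target genes. Every generated object is reproducible byte-for-byte from
# the config seed.

#' Configuration for the synthetic dataset
#'
#' Defaults mirror the study conditions: 341 miRNAs x (7 FH + 7 SFH)
#' samples, 741 genes x (7 FH + 6 SFH) samples, 16 planted differentially
#' expressed miRNAs with |log2FC| uniform in \[0.5, 2\], NB dispersion 0.1,
#' log-normal library-size factors, and negative miRNA->target coupling
#' with slope 2 on the standardized latent scale.
#'
#' @param n_fh_mirna,n_sfh_mirna miRNA sample counts per group (7, 7).
#' @param n_fh_mrna,n_sfh_mrna mRNA sample counts per group (7, 6).
#' @param n_mirna,n_gene Feature counts (341, 741).
#' @param frac_de_mirna Fraction of miRNAs with a planted fold change
#'   (default 16/341).
#' @param de_log2fc_range Range |log2FC| is drawn from; the lower bound
#'   must be >= 0.5 so planted effects clear the DEMI threshold
#'   (default c(0.5, 2)).
#' @param nb_dispersion NB dispersion alpha (default 0.1).
#' @param mean_log_mu Log-normal baseline-mean parameters,
#'   `c(meanlog, sdlog)` (default c(4, 1.5)).
#' @param planted_mean_log Baseline-mean parameters for planted features
#'   (default c(5, 0.5)); planted miRNAs and targets are kept clearly
#'   expressed so their coupling is observable at these sample sizes.
#' @param coupling_slope Suppression slope (> 0) of target latent
#'   log-abundance per SD of miRNA latent (default 2).
#' @param coupling_noise SD of residual Gaussian noise on the target
#'   latent (default 0.3).
#' @param rewired_fraction Fraction of planted pairs active in only one
#'   group (default 0.15); the rest are active in both. Kept small so the
#'   planted rewired nodes can all fit within the top decile of the
#'   network node universe, the scale on which rewiring recovery is
#'   defined.
#' @param n_target_genes Number of planted target genes (default 16, one
#'   per planted DE miRNA). The generator does not model target-specific
#'   regulation, so several targets of one miRNA would be near-collinear
#'   (profiles sharing the same latent) — degenerate input that partial
#'   correlation rightly prunes; one target per miRNA keeps planted pairs
#'   identifiable.
#' @param lib_size_sdlog SD of log library-size factors (default 0.2).
#' @param n_decoy_utr Decoy UTRs generated for non-target genes
#'   (default 50).
#' @param utr_len_range UTR length range in nt (default c(500, 2000)).
#' @param seed RNG seed (default 1).
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_fh_mirna = 7, n_sfh_mirna = 7,
                             n_fh_mrna = 7, n_sfh_mrna = 6,
                             n_mirna = 341, n_gene = 741,
                             frac_de_mirna = 16 / 341,
                             de_log2fc_range = c(0.5, 2),
                             nb_dispersion = 0.1,
                             mean_log_mu = c(4, 1.5),
                             planted_mean_log = c(5, 0.5),
                             coupling_slope = 2,
                             coupling_noise = 0.3,
                             rewired_fraction = 0.15,
                             n_target_genes = 16,
                             lib_size_sdlog = 0.2,
                             n_decoy_utr = 50,
                             utr_len_range = c(500, 2000),
                             seed = 1) {
  cfg <- as.list(environment())
  pos <- c("n_fh_mirna", "n_sfh_mirna", "n_fh_mrna", "n_sfh_mrna",
           "n_mirna", "n_gene", "nb_dispersion")
  for (nm in pos) if (cfg[[nm]] <= 0) abort("%s must be strictly positive", nm)
  if (frac_de_mirna < 0 || frac_de_mirna > 1)
    abort("frac_de_mirna must be in [0, 1]")
  if (de_log2fc_range[1] < 0.5)
    abort("de_log2fc_range lower bound must be >= 0.5 (the DEMI threshold)")
  if (coupling_slope <= 0)
    abort("coupling_slope must be > 0 (planted pairs are negatively coupled)")
  if (rewired_fraction < 0 || rewired_fraction > 1)
    abort("rewired_fraction must be in [0, 1]")
  structure(cfg, class = "synthetic_config")
}

#' Generate the two-group count matrices and planted truth
#'
#' miRNA counts are NB with mean `mu * 2^(log2FC * I(SFH)) * sf_sample`.
#' For a planted pair the target's latent log2-abundance in an active
#' group is `log2(baseline) - coupling_slope * z + noise`, where z is the
#' miRNA's realized log2-CPM standardized within that group (so the target
#' tracks the miRNA's actual per-sample abundance); the latent is
#' exponentiated (base 2, the standard expression scale) into the NB mean
#' — giving negative within-group CPM correlation only where the pair is
#' active. All other features are independent.
#'
#' @param config A [synthetic_config()].
#' @return List with `mirna` and `mrna` ([count_matrix()] objects) and
#'   `truth` (class `synthetic_truth`): `de_mirnas` (`mirna_id`,
#'   `log2fc`), `target_pairs` (`mirna_id`, `gene_id`, `active_group` in
#'   FH/SFH/both), `rewired_nodes`, `mirna_ids`, `gene_ids`,
#'   `n_zero_rows`, `seed`.
#' @export
synthetic_counts <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)

  mirna_ids <- sprintf("syn-miR-%03d", seq_len(config$n_mirna))
  gene_ids <- sprintf("SYNG%04d", seq_len(config$n_gene))
  mi_samples <- c(sprintf("FH%d", seq_len(config$n_fh_mirna)),
                  sprintf("SFH%d", seq_len(config$n_sfh_mirna)))
  mi_groups <- rep(c("FH", "SFH"), c(config$n_fh_mirna, config$n_sfh_mirna))
  g_samples <- c(sprintf("FH%d", seq_len(config$n_fh_mrna)),
                 sprintf("SFH%d", seq_len(config$n_sfh_mrna)))
  g_groups <- rep(c("FH", "SFH"), c(config$n_fh_mrna, config$n_sfh_mrna))

  n_de <- round(config$frac_de_mirna * config$n_mirna)
  de_idx <- if (n_de > 0) sort(sample.int(config$n_mirna, n_de)) else integer(0)
  lfc <- numeric(config$n_mirna)
  if (n_de > 0)
    lfc[de_idx] <- runif(n_de, config$de_log2fc_range[1], config$de_log2fc_range[2]) *
      sample(c(-1, 1), n_de, replace = TRUE)

  # planted pairs: targets coupled to planted DE miRNAs (round-robin)
  n_tg <- min(config$n_target_genes, config$n_gene)
  tg_idx <- if (n_de > 0 && n_tg > 0) sort(sample.int(config$n_gene, n_tg)) else integer(0)
  pairs <- if (length(tg_idx)) {
    data.frame(mirna_id = mirna_ids[de_idx][rep_len(seq_len(n_de), n_tg)],
               gene_id = gene_ids[tg_idx])
  } else {
    data.frame(mirna_id = character(), gene_id = character())
  }
  n_rw <- round(config$rewired_fraction * nrow(pairs))
  active <- rep("both", nrow(pairs))
  if (n_rw > 0) {
    rw <- sample.int(nrow(pairs), n_rw)
    active[rw] <- sample(c("FH", "SFH"), n_rw, replace = TRUE)
  }
  pairs$active_group <- active

  # baseline means; planted features drawn from the expressed range
  mu_mi <- exp(rnorm(config$n_mirna, config$mean_log_mu[1], config$mean_log_mu[2]))
  mu_g <- exp(rnorm(config$n_gene, config$mean_log_mu[1], config$mean_log_mu[2]))
  mu_mi[de_idx] <- exp(rnorm(n_de, config$planted_mean_log[1],
                             config$planted_mean_log[2]))
  mu_g[tg_idx] <- exp(rnorm(length(tg_idx), config$planted_mean_log[1],
                            config$planted_mean_log[2]))

  sf_mi <- exp(rnorm(length(mi_samples), 0, config$lib_size_sdlog))
  sf_g <- setNames(exp(rnorm(length(g_samples), 0, config$lib_size_sdlog)),
                   g_samples)

  size <- 1 / config$nb_dispersion

  # miRNA counts
  mu_mat <- outer(mu_mi, rep(1, length(mi_samples)))
  mu_mat[de_idx, mi_groups == "SFH"] <-
    mu_mat[de_idx, mi_groups == "SFH"] * 2^lfc[de_idx]
  mu_mat <- sweep(mu_mat, 2, sf_mi, "*")
  mirna_counts <- matrix(rnbinom(length(mu_mat), mu = mu_mat, size = size),
                         nrow = config$n_mirna,
                         dimnames = list(mirna_ids, mi_samples))

  # realized miRNA log2-CPM, the latent the planted targets respond to
  mi_cpm <- sweep(mirna_counts, 2, colSums(mirna_counts), "/") * 1e6
  zscore <- function(v) {
    s <- sd(v)
    if (is.na(s) || s < 1e-8) return(rep(0, length(v)))
    (v - mean(v)) / s
  }

  # mRNA counts: in an active group a planted target's latent log-mean is
  # baseline - slope * z(miRNA log2 CPM) + Gaussian noise
  mu_gmat <- outer(mu_g, rep(1, length(g_samples)))
  dimnames(mu_gmat) <- list(gene_ids, g_samples)
  for (i in seq_len(nrow(pairs))) {
    gid <- pairs$gene_id[i]; mid <- pairs$mirna_id[i]
    act <- pairs$active_group[i]
    for (grp in c("FH", "SFH")) {
      s_grp <- g_samples[g_groups == grp]
      noise <- rnorm(length(s_grp), 0, config$coupling_noise)
      if (act == "both" || act == grp) {
        z <- zscore(log2(mi_cpm[mid, s_grp] + 1))
        mu_gmat[gid, s_grp] <- mu_g[match(gid, gene_ids)] *
          2^(-config$coupling_slope * z + noise)
      } else {
        mu_gmat[gid, s_grp] <- mu_g[match(gid, gene_ids)] * 2^noise
      }
    }
  }
  mu_gmat <- sweep(mu_gmat, 2, sf_g[g_samples], "*")
  mrna_counts <- matrix(rnbinom(length(mu_gmat), mu = mu_gmat, size = size),
                        nrow = config$n_gene,
                        dimnames = list(gene_ids, g_samples))

  # rewired by construction: the genes whose only planted edge is
  # group-specific (their miRNAs usually keep stable edges to other genes)
  rewired <- unique(pairs$gene_id[pairs$active_group != "both"])

  truth <- structure(list(
    de_mirnas = data.frame(mirna_id = mirna_ids[de_idx], log2fc = lfc[de_idx]),
    target_pairs = pairs,
    rewired_nodes = rewired,
    planted_sites = NULL,  # filled by synthetic_sequences()
    enriched_term = NULL,  # filled by synthetic_pathways()
    mirna_ids = mirna_ids, gene_ids = gene_ids,
    n_zero_rows = c(mirna = sum(rowSums(mirna_counts) == 0),
                    gene = sum(rowSums(mrna_counts) == 0)),
    seed = config$seed), class = "synthetic_truth")

  list(mirna = count_matrix(mirna_counts, setNames(mi_groups, mi_samples), "miRNA"),
       mrna = count_matrix(mrna_counts, setNames(g_groups, g_samples), "gene"),
       truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic_truth: %d planted DE miRNAs, %d target pairs ",
                     "(%d rewired nodes), seed %d\n"),
              nrow(x$de_mirnas), nrow(x$target_pairs),
              length(x$rewired_nodes), x$seed))
  invisible(x)
}

# sample a random RNA string
random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# the 6-nt target-side match of a miRNA seed (reverse complement of nt 2-7)
seed_match_of <- function(mirna_seq) rna_revcomp(substr(mirna_seq, 2, 7))

# target-side site string for a planted class
site_string <- function(mirna_seq, class) {
  sm <- seed_match_of(mirna_seq)
  m8 <- chartr("ACGU", "UGCA", substr(mirna_seq, 8, 8))
  switch(class,
         "6mer" = sm,
         "7mer-m8" = paste0(m8, sm),
         "7mer-A1" = paste0(sm, "A"),
         "8mer" = paste0(m8, sm, "A"))
}

#' Generate miRNA and UTR sequences with planted seed sites
#'
#' Planted miRNAs get random 21-22 nt sequences whose seed matches are
#' mutually distinct; every planted target gene gets one UTR carrying a
#' planted site of a recorded class at a recorded position; decoy UTRs
#' (and the rest of each target UTR) are rejection-sampled segment-wise so
#' they contain no 6mer-or-better match to any planted miRNA seed. For a
#' 7mer-A1/6mer site the nucleotide 5' of the site is also resampled away
#' from the m8 match (and the one 3' away from A for 6mer/7mer-m8) so the
#' planted class is exactly the best class at that locus.
#'
#' @param truth `synthetic_truth` from [synthetic_counts()].
#' @param config The same [synthetic_config()].
#' @param max_retry Per-segment rejection cap (default 1000); exceeding it
#'   errors naming the offending miRNA.
#' @return List with `mirna_seqs`, `utr_seqs` (named character vectors;
#'   transcript ids are `<gene>.t1`) and updated `truth` whose
#'   `planted_sites` records (`mirna_id`, `transcript_id`, `site_type`,
#'   `utr_start`).
#' @export
synthetic_sequences <- function(truth, config = synthetic_config(),
                                max_retry = 1000) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(config$seed + 1L)

  planted_mirnas <- unique(truth$target_pairs$mirna_id)
  extra <- setdiff(truth$de_mirnas$mirna_id, planted_mirnas)
  mirna_seqs <- character(0)
  seen_seeds <- character(0)
  for (mid in c(planted_mirnas, extra)) {
    repeat {
      s <- random_rna(sample(21:22, 1))
      sm <- seed_match_of(s)
      if (!(sm %in% seen_seeds)) break
    }
    seen_seeds <- c(seen_seeds, seed_match_of(s))
    mirna_seqs[mid] <- s
  }
  forbidden <- vapply(mirna_seqs[planted_mirnas], seed_match_of, "")

  # build a sequence segment-wise; redraw a segment while it creates any
  # forbidden seed match. The check window carries only the last 5 context
  # characters so a hit must overlap the new segment (a planted site
  # already present in the context never blocks extension).
  clean_rna <- function(n, context = "", who = "decoy UTR") {
    out <- context
    remaining <- n
    while (remaining > 0) {
      take <- min(remaining, 120L)
      tries <- 0L
      repeat {
        seg <- random_rna(take)
        window <- paste0(substr(out, max(1, nchar(out) - 4), nchar(out)), seg)
        hit <- vapply(forbidden, function(f) grepl(f, window, fixed = TRUE), TRUE)
        if (!any(hit)) break
        tries <- tries + 1L
        if (tries >= max_retry)
          abort("rejection sampling exceeded %d retries for %s (miRNA %s)",
                max_retry, who, planted_mirnas[which(hit)[1]])
      }
      out <- paste0(out, seg)
      remaining <- remaining - take
    }
    substr(out, nchar(context) + 1, nchar(out))
  }

  classes <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  utr_seqs <- character(0)
  sites <- list()
  pairs <- truth$target_pairs
  for (i in seq_len(nrow(pairs))) {
    gid <- pairs$gene_id[i]; mid <- pairs$mirna_id[i]
    tid <- paste0(gid, ".t1")
    len <- sample(config$utr_len_range[1]:config$utr_len_range[2], 1)
    cls <- sample(classes, 1)
    site <- site_string(mirna_seqs[[mid]], cls)
    # place the site away from both UTR ends so flank checks are defined
    pos <- sample(seq(10, len - nchar(site) - 10), 1)
    left <- clean_rna(pos - 1, who = tid)
    # guard flanks so the planted class is the best class at the locus
    m8 <- chartr("ACGU", "UGCA", substr(mirna_seqs[[mid]], 8, 8))
    if (cls %in% c("7mer-A1", "6mer") &&
        substr(left, nchar(left), nchar(left)) == m8) {
      repl <- sample(setdiff(c("A", "C", "G", "U"), m8), 1)
      substr(left, nchar(left), nchar(left)) <- repl
    }
    right <- clean_rna(len - pos + 1 - nchar(site),
                       context = paste0(left, site), who = tid)
    if (cls %in% c("7mer-m8", "6mer") && substr(right, 1, 1) == "A")
      substr(right, 1, 1) <- sample(c("C", "G", "U"), 1)
    utr_seqs[tid] <- paste0(left, site, right)
    # the site string's first character is the site's 5'-most nucleotide
    # (the m8 match for 8mer/7mer-m8, the seed match otherwise)
    sites[[i]] <- data.frame(mirna_id = mid, transcript_id = tid,
                             site_type = cls, utr_start = pos)
  }
  planted <- if (length(sites)) do.call(rbind, sites) else
    data.frame(mirna_id = character(), transcript_id = character(),
               site_type = character(), utr_start = integer())

  # decoy UTRs for genes without planted sites
  decoy_genes <- setdiff(truth$gene_ids, pairs$gene_id)
  n_decoy <- min(config$n_decoy_utr, length(decoy_genes))
  if (n_decoy > 0) {
    for (gid in sort(sample(decoy_genes, n_decoy))) {
      tid <- paste0(gid, ".t1")
      len <- sample(config$utr_len_range[1]:config$utr_len_range[2], 1)
      utr_seqs[tid] <- clean_rna(len, who = tid)
    }
  }

  truth$planted_sites <- planted
  list(mirna_seqs = mirna_seqs, utr_seqs = utr_seqs, truth = truth)
}

#' Generate pathway gene sets with one planted enriched term
#'
#' One term is loaded with planted target genes (overlap recorded in the
#' returned truth); decoy terms are drawn uniformly from the gene
#' universe.
#'
#' @param truth `synthetic_truth` (needs `target_pairs` and `gene_ids`).
#' @param n_decoy_terms Number of uniform decoy terms (default 25).
#' @param term_size Size of every term (default 15).
#' @param planted_overlap How many planted target genes the enriched term
#'   contains (default 10, capped at min(term_size, #targets)).
#' @return List with `sets` (named list, GMT-ready), `enriched_term`, and
#'   updated `truth` (`enriched_term`, `enriched_overlap` filled in).
#' @export
synthetic_pathways <- function(truth, n_decoy_terms = 25, term_size = 15,
                               planted_overlap = 10) {
  stopifnot(inherits(truth, "synthetic_truth"))
  universe <- truth$gene_ids
  if (term_size > length(universe))
    abort("term_size %d exceeds the gene universe (%d)", term_size, length(universe))
  set.seed(truth$seed + 2L)
  targets <- unique(truth$target_pairs$gene_id)
  sets <- list()
  enriched <- NULL
  if (length(targets)) {
    k <- min(planted_overlap, term_size, length(targets))
    members <- c(sample(targets, k),
                 sample(setdiff(universe, targets), term_size - k))
    enriched <- "SYNPATH_PLANTED"
    sets[[enriched]] <- sort(members)
    truth$enriched_overlap <- as.integer(k)
  } else {
    warning("no planted target genes; generating decoy terms only")
  }
  for (i in seq_len(n_decoy_terms))
    sets[[sprintf("SYNPATH_%03d", i)]] <- sort(sample(universe, term_size))
  truth$enriched_term <- enriched
  list(sets = sets, enriched_term = enriched, truth = truth)
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper running [synthetic_counts()],
#' [synthetic_sequences()] and [synthetic_pathways()], optionally writing
#' everything under `out_dir` (counts + sample sheets as TSV, sequences as
#' FASTA, pathways as GMT, truth as JSON-like TSVs).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory.
#' @return List with `mirna`, `mrna`, `mirna_seqs`, `utr_seqs`,
#'   `pathways`, `truth`.
#' @export
synthetic_dataset <- function(config = synthetic_config(), out_dir = NULL) {
  cnt <- synthetic_counts(config)
  seqs <- synthetic_sequences(cnt$truth, config)
  paths <- synthetic_pathways(seqs$truth)
  out <- list(mirna = cnt$mirna, mrna = cnt$mrna,
              mirna_seqs = seqs$mirna_seqs, utr_seqs = seqs$utr_seqs,
              pathways = paths$sets, truth = paths$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_counts(out$mirna, file.path(out_dir, "mirna_counts.tsv"),
                 file.path(out_dir, "mirna_samples.tsv"))
    write_counts(out$mrna, file.path(out_dir, "mrna_counts.tsv"),
                 file.path(out_dir, "mrna_samples.tsv"))
    write_fasta(out$mirna_seqs, file.path(out_dir, "mirna.fa"),
                comment = "mature miRNA, RNA alphabet, 5'->3'")
    write_fasta(out$utr_seqs, file.path(out_dir, "utr.fa"),
                comment = "synthetic UTR, RNA alphabet, 5'->3'")
    write_gmt(out$pathways, file.path(out_dir, "pathways.gmt"))
    write_truth(out$truth, file.path(out_dir, "truth"))
  }
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param comment Optional comment emitted as a leading `;` line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste(";", comment), con)
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path (`;` comment lines are ignored).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^;", lines)]
  hdr <- grepl("^>", lines)
  ids <- sub("^>([^ ]+).*", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  setNames(seqs, ids)
}

# truth serialization: one TSV per component plus a key-value header
write_truth <- function(truth, stem) {
  write.table(truth$de_mirnas, paste0(stem, "_de_mirnas.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$target_pairs, paste0(stem, "_target_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth$planted_sites))
    write.table(truth$planted_sites, paste0(stem, "_planted_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(sprintf("seed\t%d", truth$seed),
            sprintf("enriched_term\t%s", truth$enriched_term %||% "NA"),
            sprintf("enriched_overlap\t%s", truth$enriched_overlap %||% "NA"),
            sprintf("rewired_nodes\t%s", paste(truth$rewired_nodes, collapse = ",")))
  writeLines(meta, paste0(stem, "_meta.tsv"))
  invisible(stem)
}
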