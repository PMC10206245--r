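# End-to-end orchestration: QC -> DE -> target prediction -> PCIT per
# group -> connectivity/rewiring -> duplex mfe -> enrichment.

#' Pipeline configuration
#'
#' Collects input paths and all stage thresholds. Threshold defaults are
#' the study's printed values: raw p 0.05 and |log2FC| 0.5 for DEMIs,
#' context++ -0.4, edge |r| 0.6, z 1.96, mfe -20 kcal/mol, kappa 0.4, CPM
#' prevalence 1 CPM in 50% of samples.
#'
#' @param synthetic Run on a generated dataset (`TRUE`) or on user files.
#' @param synthetic_cfg A [synthetic_config()] (synthetic mode).
#' @param mirna_counts,mirna_sheet,mrna_counts,mrna_sheet,mirna_fasta,
#'   utr_fasta,targetscan,gmt Input paths (file mode; `targetscan` is
#'   optional when FASTA sequences are given, and vice versa).
#' @param p_thresh,fc_thresh DEMI thresholds (0.05, 0.5).
#' @param context_thresh TargetScan score threshold (-0.4).
#' @param r_min Network edge threshold (0.6).
#' @param z_crit Differential-connectivity threshold (1.96).
#' @param mfe_cutoff Duplex affinity cutoff (-20).
#' @param kappa_min Term-clustering threshold (0.4).
#' @param min_cpm,min_frac CPM prevalence filter (1, 0.5).
#' @param enrich_alpha Holm significance level (0.05).
#' @param seed RNG seed for every stochastic stage.
#' @param out_dir Output directory (default a temp dir).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE,
                            synthetic_cfg = synthetic_config(seed = seed),
                            mirna_counts = NULL, mirna_sheet = NULL,
                            mrna_counts = NULL, mrna_sheet = NULL,
                            mirna_fasta = NULL, utr_fasta = NULL,
                            targetscan = NULL, gmt = NULL,
                            p_thresh = 0.05, fc_thresh = 0.5,
                            context_thresh = -0.4, r_min = 0.6,
                            z_crit = 1.96, mfe_cutoff = -20,
                            kappa_min = 0.4, min_cpm = 1, min_frac = 0.5,
                            enrich_alpha = 0.05, seed = 1,
                            out_dir = tempfile("mirewire_run_")) {
  cfg <- as.list(environment())
  if (!synthetic) {
    need <- c("mirna_counts", "mirna_sheet", "mrna_counts", "mrna_sheet")
    miss <- need[vapply(cfg[need], is.null, TRUE)]
    if (length(miss))
      abort("file mode requires: %s", paste(miss, collapse = ", "))
    if (is.null(targetscan) && (is.null(mirna_fasta) || is.null(utr_fasta)))
      abort("file mode needs either a TargetScan table or miRNA + UTR FASTA")
  }
  structure(cfg, class = "pipeline_config")
}

# stable hash of the configuration (thresholds + paths), for the manifest
config_hash <- function(config) {
  keep <- config[sort(setdiff(names(config), "out_dir"))]
  flat <- vapply(names(keep), function(nm) {
    v <- keep[[nm]]
    if (inherits(v, "synthetic_config")) v <- unlist(v)
    paste0(nm, "=", paste(format(v, digits = 15), collapse = ","))
  }, "")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(flat, tmp)
  unname(tools::md5sum(tmp))
}

stage_file <- function(out_dir, name) file.path(out_dir, name)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes one TSV per stage output under
#' `config$out_dir`:
#' `filtered_mirna_counts.tsv`, `de_results.tsv`, `target_predictions.tsv`,
#' `network_FH.tsv` / `network_SFH.tsv`, `connectivity.tsv`,
#' `rewiring.tsv`, `central_reference.tsv`, `duplex_mfe.tsv`,
#' `enrichment_FH.tsv` / `enrichment_SFH.tsv`, `pair_summary.tsv`, plus
#' `run_config.tsv` and `manifest.tsv`. Any stage failure aborts with an
#' error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_run`: list with `manifest`
#'   (`data.frame`: file, rows), `config_hash`, `out_dir`, and the
#'   in-memory stage results (`de`, `predictions`, `networks`,
#'   `connectivity`, `rewiring`, `mfe`, `enrichment`, `pairs`, `truth`
#'   when synthetic).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) abort("stage '%s' failed: %s", name,
                                       conditionMessage(e)))
  }
  manifest <- list()
  note <- function(path, rows) {
    manifest[[length(manifest) + 1L]] <<- data.frame(file = basename(path),
                                                     rows = rows)
  }

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  if (config$synthetic) {
    dat <- stage("synthetic_data", synthetic_dataset(config$synthetic_cfg))
    mirna_raw <- dat$mirna; mrna_raw <- dat$mrna
    mirna_seqs <- dat$mirna_seqs; utr_seqs <- dat$utr_seqs
    pathways <- dat$pathways; truth <- dat$truth
    targetscan_tab <- NULL
  } else {
    mirna_raw <- stage("input", read_counts(config$mirna_counts,
                                            config$mirna_sheet, "miRNA"))
    mrna_raw <- stage("input", read_counts(config$mrna_counts,
                                           config$mrna_sheet, "gene"))
    mirna_seqs <- if (!is.null(config$mirna_fasta))
      stage("input", read_fasta(config$mirna_fasta)) else NULL
    utr_seqs <- if (!is.null(config$utr_fasta))
      stage("input", read_fasta(config$utr_fasta)) else NULL
    pathways <- if (!is.null(config$gmt)) stage("input", read_gmt(config$gmt))
      else abort("stage 'input' failed: no GMT pathway file configured")
    targetscan_tab <- config$targetscan
  }

  # --- expression QC ------------------------------------------------------
  mirna_nz <- stage("expression_qc", drop_zero_features(mirna_raw))
  mirna_f <- stage("expression_qc",
                   prevalence_filter(mirna_nz, config$min_cpm, config$min_frac))
  mrna_nz <- stage("expression_qc", drop_zero_features(mrna_raw))
  mrna_f <- stage("expression_qc",
                  prevalence_filter(mrna_nz, config$min_cpm, config$min_frac))
  cpm_mirna <- stage("expression_qc", cpm(mirna_f))
  cpm_mrna <- stage("expression_qc", cpm(mrna_f))
  note(write_tsv(data.frame(feature = rownames(mirna_f$counts), mirna_f$counts,
                            check.names = FALSE),
                 stage_file(config$out_dir, "filtered_mirna_counts.tsv")),
       nrow(mirna_f$counts))

  # --- differential expression -------------------------------------------
  de <- stage("diff_expression",
              classify_demis(nb_wald_test(mirna_f),
                             p_thresh = config$p_thresh,
                             fc_thresh = config$fc_thresh))
  demis <- de$feature_id[de$status != "not_significant"]
  note(write_tsv(as.data.frame(de), stage_file(config$out_dir, "de_results.tsv")),
       nrow(de))
  if (!length(demis)) abort("stage 'diff_expression' failed: no DEMIs called")

  # --- target prediction --------------------------------------------------
  expressed <- rownames(mrna_f$counts)
  if (!is.null(targetscan_tab)) {
    pred <- stage("target_prediction",
                  load_targetscan(targetscan_tab,
                                  score_threshold = config$context_thresh))
  } else {
    if (is.null(mirna_seqs) || is.null(utr_seqs))
      abort("stage 'target_prediction' failed: no TargetScan table or sequences")
    hits <- stage("target_prediction",
                  scan_target_sites(mirna_seqs[intersect(demis, names(mirna_seqs))],
                                    utr_seqs))
    pred <- unique(data.frame(mirna_id = hits$mirna_id,
                              gene_id = sub("\\.[^.]*$", "", hits$transcript_id)))
  }
  pred <- stage("target_prediction", intersect_expressed(pred, expressed))
  pred <- pred[pred$mirna_id %in% demis, , drop = FALSE]
  note(write_tsv(pred, stage_file(config$out_dir, "target_predictions.tsv")),
       nrow(pred))
  if (!nrow(pred))
    abort("stage 'target_prediction' failed: no expressed predicted targets")
  target_genes <- sort(unique(pred$gene_id))

  # --- PCIT networks per group -------------------------------------------
  nets <- lapply(c(FH = "FH", SFH = "SFH"), function(g) {
    stage(paste0("pcit_network_", g),
          build_group_network(cpm_mirna, cpm_mrna,
                              demis = intersect(demis, rownames(cpm_mirna$cpm)),
                              target_genes = target_genes,
                              group = g, r_min = config$r_min))
  })
  for (g in names(nets))
    note(write_tsv(nets[[g]]$edges,
                   stage_file(config$out_dir, sprintf("network_%s.tsv", g))),
         nrow(nets[[g]]$edges))

  # --- connectivity and rewiring -----------------------------------------
  conn <- stage("connectivity_rewiring",
                differential_connectivity(nets$FH, nets$SFH,
                                          z_crit = config$z_crit))
  rewiring <- stage("connectivity_rewiring", dyn_rewiring(nets$FH, nets$SFH))
  central <- stage("connectivity_rewiring", central_reference(nets$FH, nets$SFH))
  note(write_tsv(conn, stage_file(config$out_dir, "connectivity.tsv")), nrow(conn))
  note(write_tsv(rewiring, stage_file(config$out_dir, "rewiring.tsv")),
       nrow(rewiring))
  note(write_tsv(central$edges,
                 stage_file(config$out_dir, "central_reference.tsv")),
       nrow(central$edges))

  # --- duplex mfe ---------------------------------------------------------
  mfe_gene <- NULL
  if (!is.null(mirna_seqs) && !is.null(utr_seqs)) {
    tx_gene <- sub("\\.[^.]*$", "", names(utr_seqs))
    pairs_to_score <- unique(pred[c("mirna_id", "gene_id")])
    tx_pairs <- do.call(rbind, lapply(seq_len(nrow(pairs_to_score)), function(i) {
      tids <- names(utr_seqs)[tx_gene == pairs_to_score$gene_id[i]]
      if (!length(tids)) return(NULL)
      data.frame(mirna_id = pairs_to_score$mirna_id[i], transcript_id = tids)
    }))
    recs <- stage("hybrid_mfe",
                  duplex_mfe_set(mirna_seqs, utr_seqs, pairs = tx_pairs))
    mfe_gene <- stage("hybrid_mfe",
                      gene_average_mfe(recs, mfe_cutoff = config$mfe_cutoff))
    note(write_tsv(merge(recs, mfe_gene, by = c("mirna_id", "gene_id")),
                   stage_file(config$out_dir, "duplex_mfe.tsv")), nrow(recs))
  }

  # --- enrichment ---------------------------------------------------------
  universe <- rownames(mrna_f$counts)
  enr <- lapply(c(FH = "FH", SFH = "SFH"), function(g) {
    corr_genes <- unique(with(nets[[g]]$edges,
                              c(node_a[node_a %in% target_genes],
                                node_b[node_b %in% target_genes])))
    if (!length(corr_genes)) return(NULL)
    stage(paste0("enrichment_", g),
          enrich_terms(corr_genes, pathways, universe = universe,
                       alpha = config$enrich_alpha,
                       kappa_min = config$kappa_min))
  })
  for (g in names(enr)) {
    if (is.null(enr[[g]])) next
    note(write_tsv(as.data.frame(enr[[g]]),
                   stage_file(config$out_dir, sprintf("enrichment_%s.tsv", g))),
         nrow(enr[[g]]))
  }

  # --- integrated pair table ---------------------------------------------
  pairs <- stage("summary", summarize_pairs(de, pred, nets, mfe_gene))
  note(write_tsv(pairs, stage_file(config$out_dir, "pair_summary.tsv")),
       nrow(pairs))

  hash <- config_hash(config)
  cfg_flat <- data.frame(
    key = c("p_thresh", "fc_thresh", "context_thresh", "r_min", "z_crit",
            "mfe_cutoff", "kappa_min", "min_cpm", "min_frac", "enrich_alpha",
            "seed", "config_hash"),
    value = c(config$p_thresh, config$fc_thresh, config$context_thresh,
              config$r_min, config$z_crit, config$mfe_cutoff,
              config$kappa_min, config$min_cpm, config$min_frac,
              config$enrich_alpha, config$seed, hash))
  write_tsv(cfg_flat, stage_file(config$out_dir, "run_config.tsv"))

  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, stage_file(config$out_dir, "manifest.tsv"))

  structure(list(manifest = manifest, config_hash = hash,
                 out_dir = config$out_dir, de = de, predictions = pred,
                 networks = nets, connectivity = conn, rewiring = rewiring,
                 central = central, mfe = mfe_gene, enrichment = enr,
                 pairs = pairs, truth = truth),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run [%s]: %d output files\n", x$config_hash,
              nrow(x$manifest)))
  print.data.frame(x$manifest)
  invisible(x)
}

#' Integrated miRNA-gene pair table
#'
#' One row per predicted (miRNA, gene) pair: DEMI status, per-group edge
#' correlation and PCIT significance (NA when the pair is absent from a
#' group's network), gene-average duplex mfe and its cutoff flag. The
#' headline pairs of the analysis are rows with `predicted`, a negative
#' network correlation, and `mfe_pass`.
#'
#' @param de A `demi_results` table with `status`.
#' @param predictions Prediction `data.frame` (`mirna_id`, `gene_id`).
#' @param networks Named list with `FH` and `SFH` networks
#'   (`group_network` or edge `data.frame`s).
#' @param mfe Optional [gene_average_mfe()] table.
#' @return `data.frame`, one row per predicted pair.
#' @export
summarize_pairs <- function(de, predictions, networks, mfe = NULL) {
  stopifnot(all(c("mirna_id", "gene_id") %in% names(predictions)))
  out <- unique(predictions[c("mirna_id", "gene_id")])
  orphan <- setdiff(out$mirna_id, de$feature_id)
  if (length(orphan))
    abort("predictions reference miRNAs absent from the DE table: %s",
          paste(orphan, collapse = ", "))
  out$demi_status <- as.character(de$status[match(out$mirna_id, de$feature_id)])
  out$predicted <- TRUE
  edge_lookup <- function(net) {
    e <- as_net(net)$edges
    key <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b))
    idx <- match(paste(pmin(out$mirna_id, out$gene_id),
                       pmax(out$mirna_id, out$gene_id)), key)
    list(r = e$r[idx],
         sig = if ("pcit_significant" %in% names(e)) e$pcit_significant[idx]
               else !is.na(idx))
  }
  fh <- edge_lookup(networks$FH); sfh <- edge_lookup(networks$SFH)
  out$r_fh <- fh$r; out$pcit_fh <- fh$sig
  out$r_sfh <- sfh$r; out$pcit_sfh <- sfh$sig
  if (!is.null(mfe)) {
    idx <- match(paste(out$mirna_id, out$gene_id),
                 paste(mfe$mirna_id, mfe$gene_id))
    out$gene_avg_mfe <- mfe$gene_avg_mfe[idx]
    out$mfe_pass <- mfe$passes_cutoff[idx]
  } else {
    out$gene_avg_mfe <- NA_real_
    out$mfe_pass <- NA
  }
  out$headline <- out$predicted &
    ((!is.na(out$r_fh) & out$r_fh < 0) | (!is.na(out$r_sfh) & out$r_sfh < 0)) &
    (!is.na(out$mfe_pass) & out$mfe_pass)
  out <- out[order(out$mirna_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}
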