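# PCIT co-expression network inference.
#
# PCIT (partial correlation and information theory) keeps an association
# between two features only if no third feature explains it: for every
# trio, first-order partial correlations define a local tolerance epsilon,
# and an edge is eliminated when its direct correlation is dominated by
# the tolerance-scaled correlations through some third node. Surviving
# edges are the "significant" associations.

#' Pearson correlation matrix for a group of samples
#'
#' @param x Numeric matrix (features x samples) or a `cpm_matrix` from
#'   [cpm()].
#' @param samples Optional character vector of sample ids (columns) to use;
#'   default all. At least 3 samples are required.
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   features get r = 0 against all other features (with a warning) and
#'   are listed in attribute `"zero_variance"`.
#' @export
correlation_matrix <- function(x, samples = NULL) {
  if (inherits(x, "cpm_matrix")) x <- x$cpm
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(x))
    if (length(miss)) abort("unknown sample(s): %s", paste(miss, collapse = ", "))
    x <- x[, samples, drop = FALSE]
  }
  if (ncol(x) < 3)
    abort("need >= 3 samples to correlate, got %d", ncol(x))
  sds <- apply(x, 1, sd)
  flat <- sds == 0
  r <- matrix(0, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  if (any(!flat))
    r[!flat, !flat] <- cor(t(x[!flat, , drop = FALSE]))
  diag(r) <- 1
  if (any(flat)) {
    warning(sprintf("%d zero-variance feature(s) set to r = 0: %s",
                    sum(flat), paste(head(rownames(x)[flat], 5), collapse = ", ")))
    attr(r, "zero_variance") <- rownames(x)[flat]
  }
  r
}

#' First-order partial correlation
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, the
#' correlation of x and y after removing the linear effect of z.
#'
#' @param r_xy,r_xz,r_yz Pairwise Pearson correlations (vectorized).
#' @return Partial correlation(s).
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' PCIT significance of every pairwise association
#'
#' Runs the trio-elimination algorithm over all unordered triples: an edge
#' (x, y) is eliminated when some third node z yields
#' `|r_xy| < |eps * r_xz|` and `|r_xy| < |eps * r_yz|`, with eps the mean
#' absolute ratio of partial to direct correlation over the trio (a ratio
#' with zero direct correlation contributes 0). Trios containing a
#' pairwise |r| = 1 are skipped (the partials are undefined); their count
#' is returned in attribute `"skipped_trios"`.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @return Logical matrix, `TRUE` where the association is PCIT
#'   significant; diagonal `FALSE`.
#' @export
pcit <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    abort("corr must be a square matrix")
  if (max(abs(corr - t(corr))) > 1e-8)
    abort("corr must be symmetric")
  if (any(abs(diag(corr) - 1) > 1e-8))
    abort("corr must have unit diagonal")
  sig <- .pcit_core(corr)
  dimnames(sig) <- dimnames(corr)
  sig
}

#' Build a per-group miRNA co-expression network
#'
#' Combines DEMI CPM profiles and expressed target-gene CPM profiles over
#' the group's samples (only samples with both profiles are used), runs
#' PCIT, and returns the edges that are PCIT-significant, exceed the
#' correlation threshold, and involve at least one miRNA (miRNA-gene or
#' miRNA-miRNA). Gene-gene pairs are recorded in the full dump but not
#' returned as network edges.
#'
#' @param cpm_mirna,cpm_mrna `cpm_matrix` objects for the miRNA and mRNA
#'   profiles (shared sample ids identify the same animal).
#' @param demis Character vector of DEMI feature ids (rows of
#'   `cpm_mirna`).
#' @param target_genes Character vector of expressed predicted target gene
#'   ids (rows of `cpm_mrna`).
#' @param group `"FH"` or `"SFH"`.
#' @param r_min Absolute-correlation threshold for edges (default 0.6,
#'   strict `|r| > r_min`).
#' @return Object of class `group_network`: list with `edges` (filtered
#'   edge `data.frame`: `node_a`, `node_b`, `r`, `p_cor`, `edge_class`,
#'   `pcit_significant`, `group`), `all_pairs` (every pair, unfiltered),
#'   `nodes`, `group`, `samples`.
#' @export
build_group_network <- function(cpm_mirna, cpm_mrna, demis, target_genes,
                                group = c("FH", "SFH"), r_min = 0.6) {
  group <- match.arg(group)
  stopifnot(inherits(cpm_mirna, "cpm_matrix"), inherits(cpm_mrna, "cpm_matrix"))
  if (!length(demis) && !length(target_genes)) abort("empty node set")
  miss_mi <- setdiff(demis, rownames(cpm_mirna$cpm))
  miss_g <- setdiff(target_genes, rownames(cpm_mrna$cpm))
  if (length(miss_mi) || length(miss_g))
    abort("features missing from CPM matrices: %s",
          paste(c(miss_mi, miss_g), collapse = ", "))

  s_mi <- names(cpm_mirna$groups)[cpm_mirna$groups == group]
  s_g <- names(cpm_mrna$groups)[cpm_mrna$groups == group]
  samples <- intersect(s_mi, s_g)
  if (length(samples) < 3)
    abort("group %s has %d samples with both profiles; need >= 3",
          group, length(samples))

  prof <- rbind(cpm_mirna$cpm[demis, samples, drop = FALSE],
                cpm_mrna$cpm[target_genes, samples, drop = FALSE])
  corr <- correlation_matrix(prof)
  sig <- pcit(corr)

  nodes <- rownames(prof)
  is_mirna <- nodes %in% demis
  idx <- which(upper.tri(corr), arr.ind = TRUE)
  a <- nodes[idx[, 1]]; b <- nodes[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  n_mi <- is_mirna[idx[, 1]] + is_mirna[idx[, 2]]
  cls <- c("gene-gene", "miRNA-gene", "miRNA-miRNA")[n_mi + 1]
  r <- corr[idx]
  ns <- length(samples)
  tstat <- r * sqrt((ns - 2) / pmax(1 - r^2, .Machine$double.eps))
  p_cor <- 2 * pt(-abs(tstat), df = ns - 2)

  all_pairs <- data.frame(node_a = a, node_b = b, r = r, p_cor = p_cor,
                          edge_class = cls, pcit_significant = sig[idx],
                          group = group)
  all_pairs <- all_pairs[order(all_pairs$node_a, all_pairs$node_b), ]
  rownames(all_pairs) <- NULL
  keep <- all_pairs$pcit_significant & abs(all_pairs$r) > r_min &
    all_pairs$edge_class != "gene-gene"
  structure(list(edges = all_pairs[keep, , drop = FALSE],
                 all_pairs = all_pairs,
                 nodes = data.frame(node_id = nodes,
                                    node_type = ifelse(is_mirna, "miRNA", "gene")),
                 group = group, samples = samples),
            class = "group_network")
}

#' @export
print.group_network <- function(x, ...) {
  cat(sprintf("group_network [%s]: %d nodes, %d edges (of %d pairs), %d samples\n",
              x$group, nrow(x$nodes), nrow(x$edges), nrow(x$all_pairs),
              length(x$samples)))
  invisible(x)
}

#' Write a network edge list as TSV or SIF
#'
#' @param net A `group_network` or an edge `data.frame`.
#' @param path Output path.
#' @param format `"tsv"` (all columns) or `"sif"` (`node_a  sign  node_b`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  edges <- if (inherits(net, "group_network")) net$edges else net
  if (format == "tsv") {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    sif <- data.frame(node_a = edges$node_a,
                      interaction = ifelse(edges$r >= 0, "pos", "neg"),
                      node_b = edges$node_b)
    write.table(sif, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
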