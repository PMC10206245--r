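# Pathway over-representation with Holm correction and kappa-score term
# clustering.

#' Read a GMT gene-set file
#'
#' @param path GMT path (term, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors; descriptions in attribute
#'   `"descriptions"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[`, "", 2), names(sets))
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' `P(X >= overlap)` where X counts term members among `|query|` draws
#' without replacement from the universe.
#'
#' @param query Character vector of query gene ids (non-empty, within the
#'   universe).
#' @param term Character vector of term gene ids (within the universe).
#' @param universe Character vector of all background gene ids.
#' @return The p-value.
#' @export
hypergeom_test <- function(query, term, universe) {
  query <- unique(query); term <- unique(term); universe <- unique(universe)
  if (!length(query)) abort("query gene set is empty")
  if (length(setdiff(query, universe)) || length(setdiff(term, universe)))
    abort("query and term must be subsets of the universe")
  k <- length(intersect(query, term))
  phyper(k - 1, length(term), length(universe) - length(term), length(query),
         lower.tail = FALSE)
}

#' Holm (Bonferroni step-down) adjustment
#'
#' Sequentially rejective correction: with p-values sorted ascending,
#' `p_adj(i) = max_{j <= i} min(1, (m - j + 1) p(j))`, returned in input
#' order. Wraps `stats::p.adjust(method = "holm")`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "holm")
}

#' Cohen's kappa between two gene sets over a universe
#'
#' Agreement of the two membership indicators across the universe,
#' corrected for chance: 1 for identical sets, about 0 for independent
#' ones.
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe Background gene ids.
#' @return Kappa in \[-1, 1\].
#' @export
kappa_score <- function(set_a, set_b, universe) {
  n <- length(universe)
  a <- universe %in% set_a; b <- universe %in% set_b
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Cluster terms by kappa score
#'
#' Builds a graph with an edge wherever pairwise kappa >= `kappa_min` and
#' assigns cluster ids by connected components; each cluster's
#' representative is its lowest-p member (when p-values are supplied).
#'
#' @param sets Named list of term gene sets.
#' @param universe Background gene ids.
#' @param kappa_min Kappa threshold (default 0.4).
#' @param p Optional named/ordered p-values used to pick representatives.
#' @return `data.frame` with `term_id`, `cluster_id`, `representative`.
#' @export
kappa_cluster <- function(sets, universe, kappa_min = 0.4, p = NULL) {
  stopifnot(length(sets) >= 1)
  ids <- names(sets)
  n <- length(sets)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n > 1) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- apply(pairs, 1, function(ij) {
      kappa_score(sets[[ij[1]]], sets[[ij[2]]], universe) >= kappa_min
    })
    if (any(keep))
      g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
  }
  comp <- igraph::components(g)$membership
  rep_of <- vapply(seq_len(max(comp)), function(cl) {
    members <- which(comp == cl)
    if (is.null(p)) ids[members[1]]
    else ids[members[which.min(p[members])]]
  }, "")
  data.frame(term_id = ids, cluster_id = as.integer(comp),
             representative = ids %in% rep_of)
}

#' Pathway over-representation analysis of a gene set
#'
#' Hypergeometric test of the query against every term of a GMT
#' collection, Holm ("Bonferroni step-down") correction, significance at
#' `alpha`, and kappa-score clustering of terms.
#'
#' @param query Character vector of query gene ids.
#' @param sets Named list of term gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene ids (default: union of all term genes).
#' @param alpha Family-wise significance level on the Holm-adjusted p
#'   (default 0.05).
#' @param kappa_min Kappa clustering threshold (default 0.4).
#' @return `data.frame` of class `enrichment_results`: `term_id`,
#'   `term_size`, `query_size`, `universe_size`, `overlap`, `p_hyper`,
#'   `p_holm`, `significant`, `cluster_id`, `representative`,
#'   `overlap_genes`.
#' @export
enrich_terms <- function(query, sets, universe = NULL, alpha = 0.05,
                         kappa_min = 0.4) {
  universe <- unique(universe %||% unlist(sets, use.names = FALSE))
  query <- intersect(unique(query), universe)
  if (!length(query)) abort("query gene set is empty (after universe restriction)")
  sets <- lapply(sets, intersect, universe)

  p <- vapply(names(sets), function(nm) hypergeom_test(query, sets[[nm]], universe),
              0.0)
  overlap <- vapply(sets, function(s) length(intersect(query, s)), 0L)
  p_holm <- holm_adjust(p)
  cl <- kappa_cluster(sets, universe, kappa_min = kappa_min, p = p_holm)
  res <- data.frame(term_id = names(sets),
                    term_size = lengths(sets),
                    query_size = length(query),
                    universe_size = length(universe),
                    overlap = overlap,
                    p_hyper = p,
                    p_holm = p_holm,
                    significant = p_holm <= alpha,
                    cluster_id = cl$cluster_id,
                    representative = cl$representative,
                    overlap_genes = vapply(sets, function(s)
                      paste(sort(intersect(query, s)), collapse = ","), ""),
                    row.names = NULL)
  res <- res[order(res$p_holm, res$p_hyper, res$term_id), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_results", "data.frame")
  res
}

#' @export
print.enrichment_results <- function(x, ...) {
  cat(sprintf("enrichment_results: %d terms, %d significant (Holm)\n",
              nrow(x), sum(x$significant)))
  print.data.frame(head(as.data.frame(x)[, c("term_id", "term_size", "overlap",
                                             "p_hyper", "p_holm", "significant",
                                             "cluster_id")], 10))
  invisible(x)
}
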