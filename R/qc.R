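#' Remove features with zero counts in every sample
#'
#' First quality-control step: features never observed in any library carry
#' no information and are dropped before CPM normalization.
#'
#' @param m A [count_matrix()].
#' @return A [count_matrix()] with all-zero rows removed, row order
#'   otherwise preserved. The number of dropped features is recorded in
#'   attribute `"n_dropped"`.
#' @export
drop_zero_features <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  keep <- rowSums(m$counts) > 0
  if (!any(keep)) abort("all features have zero counts in every sample")
  out <- count_matrix(m$counts[keep, , drop = FALSE], m$groups, kind = m$kind)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Counts-per-million normalization
#'
#' CPM for feature f in sample s is `counts[f, s] / colsum[s] * 1e6`, the
#' library-size normalization used throughout the pipeline (filtering and
#' co-expression run on CPM; the differential-expression stage goes back to
#' raw counts with its own median-of-ratios factors).
#'
#' @param m A [count_matrix()].
#' @return An object of class `cpm_matrix`: list with `cpm` (numeric
#'   matrix, columns summing to 1e6), `lib_sizes`, `groups`, `kind`.
#' @export
cpm <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  tot <- colSums(m$counts)
  if (any(tot == 0))
    abort("sample(s) with zero total counts: %s",
          paste(colnames(m$counts)[tot == 0], collapse = ", "))
  structure(list(cpm = sweep(m$counts, 2, tot, "/") * 1e6,
                 lib_sizes = tot, groups = m$groups, kind = m$kind),
            class = "cpm_matrix")
}

#' @export
print.cpm_matrix <- function(x, ...) {
  cat(sprintf("cpm_matrix [%s]: %d features x %d samples\n",
              x$kind, nrow(x$cpm), ncol(x$cpm)))
  invisible(x)
}

#' CPM prevalence filter
#'
#' Keeps a feature iff its CPM is at least `min_cpm` in at least `min_frac`
#' of all samples (both groups pooled). CPM for the filter is computed once
#' from `m`'s own column totals; the returned object carries the raw counts
#' so downstream differential expression sees untransformed data.
#'
#' @param m A [count_matrix()] (typically zero-filtered first).
#' @param min_cpm CPM threshold (default 1).
#' @param min_frac Minimum fraction of samples meeting `min_cpm`
#'   (default 0.5); must lie in (0, 1].
#' @param lib_sizes Per-sample totals used to compute CPM for the filter.
#'   Defaults to the column sums of `m`; pass the totals of the
#'   zero-filtered matrix explicitly to filter a derived matrix against the
#'   original library sizes (the filter is idempotent under fixed totals).
#' @return A filtered [count_matrix()]; attribute `"n_dropped"` records the
#'   number of removed features.
#' @export
prevalence_filter <- function(m, min_cpm = 1, min_frac = 0.5,
                              lib_sizes = colSums(m$counts)) {
  stopifnot(inherits(m, "count_matrix"))
  if (min_frac <= 0 || min_frac > 1)
    abort("min_frac must be in (0, 1], got %g", min_frac)
  if (any(lib_sizes == 0))
    abort("sample(s) with zero total counts: %s",
          paste(colnames(m$counts)[lib_sizes == 0], collapse = ", "))
  x <- sweep(m$counts, 2, lib_sizes, "/") * 1e6
  keep <- rowMeans(x >= min_cpm) >= min_frac
  out <- count_matrix(m$counts[keep, , drop = FALSE], m$groups, kind = m$kind)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
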