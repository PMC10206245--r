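#' Build a two-group count matrix
#'
#' Container for raw feature-by-sample counts from a two-condition design
#' (fertile, `FH`, vs subfertile, `SFH`, in the motivating study). Counts
#' must be non-negative integers; every sample must carry a group label.
#'
#' @param counts Integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param groups Character or factor vector of `"FH"`/`"SFH"` labels, either
#'   named by sample id or in column order of `counts`.
#' @param kind `"miRNA"` or `"gene"` — what the rows are.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix), `groups` (factor named by sample, levels FH, SFH)
#'   and `kind`.
#' @examples
#' m <- count_matrix(matrix(rpois(12, 10), 3, 4,
#'                          dimnames = list(paste0("f", 1:3), paste0("s", 1:4))),
#'                   groups = c("FH", "FH", "SFH", "SFH"))
#' m
#' @export
count_matrix <- function(counts, groups, kind = c("miRNA", "gene")) {
  kind <- match.arg(kind)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("counts must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    abort("duplicate feature ids: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    abort("duplicate sample ids")
  if (any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers")
  storage.mode(counts) <- "integer"

  if (is.null(names(groups))) {
    if (length(groups) != ncol(counts))
      abort("groups has length %d but there are %d samples", length(groups), ncol(counts))
    names(groups) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing))
    abort("samples without a group label: %s", paste(missing, collapse = ", "))
  groups <- factor(as.character(groups[colnames(counts)]), levels = c("FH", "SFH"))
  names(groups) <- colnames(counts)
  if (anyNA(groups))
    abort("group labels must be 'FH' or 'SFH'")

  structure(list(counts = counts, groups = groups, kind = kind),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d features x %d samples (FH %d, SFH %d)\n",
              x$kind, nrow(x$counts), ncol(x$counts),
              sum(x$groups == "FH"), sum(x$groups == "SFH")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and sample sheet from TSV files
#'
#' The counts TSV has features in rows (first column = feature id, header =
#' sample ids); the sample sheet TSV has columns `sample` and `group`
#' (FH/SFH).
#'
#' @param counts_path,sheet_path Paths to the two TSV files.
#' @param kind Row feature kind, `"miRNA"` or `"gene"`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, sheet_path, kind = c("miRNA", "gene")) {
  kind <- match.arg(kind)
  tab <- read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  sheet <- read.delim(sheet_path, check.names = FALSE)
  if (!all(c("sample", "group") %in% names(sheet)))
    abort("sample sheet must have 'sample' and 'group' columns")
  count_matrix(m, setNames(sheet$group, sheet$sample), kind = kind)
}

#' Write a count matrix (and optionally its sample sheet) as TSV
#'
#' @param m A [count_matrix()].
#' @param counts_path Output TSV path for the counts.
#' @param sheet_path Optional output TSV path for the sample sheet.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(m, counts_path, sheet_path = NULL) {
  df <- data.frame(feature = rownames(m$counts), m$counts, check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sheet_path)) {
    write.table(data.frame(sample = names(m$groups), group = as.character(m$groups)),
                sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(counts_path)
}
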