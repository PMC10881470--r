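#' Construct a gene-by-column count matrix container
#'
#' Container for NanoString-style counts: endogenous plus housekeeping genes in
#' rows, one column per (sample, arm). Carries raw counts, optionally
#' normalized counts, the housekeeping gene set and column metadata.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids), columns
#'   named by column id (typically `"<sample>_<arm>"`).
#' @param housekeeping character vector of housekeeping gene ids (must be
#'   rownames of `counts`).
#' @param columns optional data.frame with `column_id`, `sample_id`, `arm`
#'   describing each column; defaults to parsing `"<sample>_<arm>"` names.
#' @param normalized optional matrix of normalized counts (same dim).
#' @param pseudocount pseudocount used when `normalized` was produced.
#' @return an object of class `count_matrix`.
#' @seealso [normalize_counts()], [ges_score()], [differential_expression()]
#' @export
count_matrix <- function(counts, housekeeping = character(),
                         columns = NULL, normalized = NULL,
                         pseudocount = NA_real_) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop_icistrat("counts must have gene ids as rownames")
  if (is.null(colnames(counts)))
    stop_icistrat("counts must have column ids as colnames")
  if (any(counts < 0)) stop_icistrat("counts must be non-negative")
  missing_hk <- setdiff(housekeeping, rownames(counts))
  if (length(missing_hk))
    stop_icistrat("housekeeping genes absent from matrix: %s",
                  paste(missing_hk, collapse = ", "))
  if (is.null(columns)) {
    parts <- strsplit(colnames(counts), "_")
    columns <- data.frame(
      column_id = colnames(counts),
      sample_id = vapply(parts, function(p) paste(p[-length(p)], collapse = "_"), ""),
      arm = vapply(parts, function(p) p[length(p)], ""),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(identical(columns$column_id, colnames(counts)))
  if (!is.null(normalized)) stopifnot(identical(dim(normalized), dim(counts)))
  structure(list(counts = counts, housekeeping = housekeeping,
                 columns = columns, normalized = normalized,
                 pseudocount = pseudocount),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes (%d housekeeping) x %d columns; %s\n",
              nrow(x$counts), length(x$housekeeping), ncol(x$counts),
              if (is.null(x$normalized)) "raw only" else
                sprintf("normalized (pseudocount %.3g)", x$pseudocount)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# matrix to run expression analyses on: normalized if present, else raw
expr_values <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  cm$normalized %||% cm$counts
}
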