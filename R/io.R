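# CSV interchange. All writers emit plain CSV (full double precision); all
# readers validate schemas and report offending rows, and every output file
# is re-readable by the package's own readers.

write_csv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (j in which(num)) out[[j]] <- format(df[[j]], digits = 17, trim = TRUE,
                                           scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_icistrat("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
}

#' Write a synthetic cohort to a directory of CSV files
#'
#' Layout: `cytokines.csv` (long: sample_id, arm, analyte, timepoint, pg_ml),
#' `histo.csv` (wide, includes viability fluorescence), `flow.csv` (wide),
#' `counts.csv` (gene x column) with `counts_columns.csv` sidecar,
#' `cells.csv` (sample_id, arm, x_um, y_um, phenotype), `metadata.csv`
#' (includes the hidden ground-truth class) and `config.ini`.
#'
#' @param cohort a `multimodal_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cyt <- list(); histo <- list(); flow <- list(); cells <- list(); meta <- list()
  tps <- c("T0", "T24", "T48", "T72")
  for (s in cohort) {
    for (arm in names(s$arms)) {
      a <- s$arms[[arm]]
      for (an in names(a$cytokines))
        cyt[[paste(s$sample_id, arm, an)]] <- data.frame(
          sample_id = s$sample_id, arm = arm, analyte = an, timepoint = tps,
          pg_ml = unname(a$cytokines[[an]]), stringsAsFactors = FALSE)
      histo[[paste(s$sample_id, arm)]] <- data.frame(
        sample_id = s$sample_id, arm = arm, t(a$histo),
        viability_au = a$viability, stringsAsFactors = FALSE)
      flow[[paste(s$sample_id, arm)]] <- data.frame(
        sample_id = s$sample_id, arm = arm, t(a$flow), stringsAsFactors = FALSE)
      cells[[paste(s$sample_id, arm)]] <- cbind(
        data.frame(sample_id = s$sample_id, arm = arm), s$cells[[arm]])
    }
    meta[[s$sample_id]] <- data.frame(sample_id = s$sample_id,
                                      true_class = s$true_class,
                                      as.data.frame(s$metadata),
                                      stringsAsFactors = FALSE)
  }
  write_csv_plain(do.call(rbind, c(cyt, make.row.names = FALSE)),
                  file.path(dir, "cytokines.csv"))
  write_csv_plain(do.call(rbind, c(histo, make.row.names = FALSE)),
                  file.path(dir, "histo.csv"))
  write_csv_plain(do.call(rbind, c(flow, make.row.names = FALSE)),
                  file.path(dir, "flow.csv"))
  write_csv_plain(do.call(rbind, c(cells, make.row.names = FALSE)),
                  file.path(dir, "cells.csv"))
  write_csv_plain(do.call(rbind, c(meta, make.row.names = FALSE)),
                  file.path(dir, "metadata.csv"))
  cm <- attr(cohort, "counts")
  counts_df <- data.frame(gene_id = rownames(cm$counts),
                          housekeeping = rownames(cm$counts) %in% cm$housekeeping,
                          cm$counts, check.names = FALSE)
  write_csv_plain(counts_df, file.path(dir, "counts.csv"))
  write_csv_plain(cm$columns, file.path(dir, "counts_columns.csv"))
  cfg <- attr(cohort, "config")
  write_run_config(list(
    cohort = list(n_samples = cfg$n_samples, noise_cv = cfg$noise_cv,
                  n_genes = cfg$n_genes, n_housekeeping = cfg$n_housekeeping,
                  nb_dispersion = cfg$nb_dispersion, seed = cfg$seed,
                  arms = paste(cfg$arms, collapse = ","),
                  signature_genes = paste(attr(cohort, "signature_genes"), collapse = ","),
                  suppression_genes = paste(attr(cohort, "suppression_genes"), collapse = ","))),
    file.path(dir, "config.ini"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Schema-validates every table (non-negative pg/ml, known phenotypes and
#' arms, percentages in range, unique keys, cross-file sample-id
#' consistency), reporting offending rows by number. Row order in the files
#' does not matter: samples, arms, analytes and timepoints are reassembled in
#' canonical order.
#'
#' @param dir cohort directory.
#' @return a `multimodal_cohort`.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop_icistrat("missing input file: %s", p)
    utils::read.csv(p, check.names = FALSE, stringsAsFactors = FALSE)
  }
  cyt <- rd("cytokines.csv"); histo <- rd("histo.csv"); flow <- rd("flow.csv")
  cells <- rd("cells.csv"); meta <- rd("metadata.csv")
  counts_df <- rd("counts.csv"); col_meta <- rd("counts_columns.csv")
  require_columns(cyt, c("sample_id", "arm", "analyte", "timepoint", "pg_ml"),
                  "cytokines.csv")
  require_columns(cells, c("sample_id", "arm", "x_um", "y_um", "phenotype"),
                  "cells.csv")
  require_columns(histo, c("sample_id", "arm", "tumor_content", "immune_content",
                           "infiltration", "pyknosis", "discohesion",
                           "cleaved_caspase3", "viability_au"), "histo.csv")
  bad <- which(!is.finite(cyt$pg_ml) | cyt$pg_ml < 0)
  if (length(bad))
    stop_icistrat("cytokines.csv: negative or non-finite pg/ml at row(s) %s",
                  paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!cells$phenotype %in% cell_phenotypes())
  if (length(bad))
    stop_icistrat("cells.csv: unknown phenotype at row(s) %s",
                  paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(cyt$sample_id, cyt$arm, cyt$analyte, cyt$timepoint)
  if (anyDuplicated(key))
    stop_icistrat("cytokines.csv: duplicated (sample, arm, analyte, timepoint) at row %d",
                  anyDuplicated(key))
  key <- paste(histo$sample_id, histo$arm)
  if (anyDuplicated(key))
    stop_icistrat("histo.csv: duplicated (sample, arm) at row %d", anyDuplicated(key))
  pct_cols <- c("tumor_content", "immune_content", "infiltration", "cleaved_caspase3")
  for (pc in pct_cols) {
    bad <- which(histo[[pc]] < 0 | histo[[pc]] > 100)
    if (length(bad))
      stop_icistrat("histo.csv: %s out of [0,100] at row(s) %s", pc,
                    paste(utils::head(bad, 5), collapse = ", "))
  }
  ids <- sort(unique(meta$sample_id))
  for (nm in list(c("cytokines.csv", "cyt"), c("histo.csv", "histo"),
                  c("cells.csv", "cells"))) {
    tab <- get(nm[2])
    extra <- setdiff(unique(tab$sample_id), ids)
    if (length(extra))
      stop_icistrat("%s: sample id(s) not in metadata.csv: %s", nm[1],
                    paste(extra, collapse = ", "))
  }
  counts <- as.matrix(counts_df[, setdiff(names(counts_df), c("gene_id", "housekeeping")),
                                drop = FALSE])
  rownames(counts) <- counts_df$gene_id
  counts <- counts[, col_meta$column_id, drop = FALSE]
  cm <- count_matrix(counts, housekeeping = counts_df$gene_id[as.logical(counts_df$housekeeping)],
                     columns = col_meta)
  tps <- c("T0", "T24", "T48", "T72")
  samples <- lapply(ids, function(sid) {
    arms_here <- sort(unique(histo$arm[histo$sample_id == sid]))
    arms <- lapply(arms_here, function(arm) {
      hc <- histo[histo$sample_id == sid & histo$arm == arm, , drop = FALSE]
      cc <- cyt[cyt$sample_id == sid & cyt$arm == arm, , drop = FALSE]
      fl <- flow[flow$sample_id == sid & flow$arm == arm, , drop = FALSE]
      cytl <- lapply(split(cc, cc$analyte), function(d) {
        v <- d$pg_ml[match(tps, d$timepoint)]
        if (anyNA(v)) stop_icistrat("cytokines.csv: %s/%s/%s missing a timepoint",
                                    sid, arm, d$analyte[1])
        names(v) <- tps
        v
      })
      col_id <- col_meta$column_id[col_meta$sample_id == sid & col_meta$arm == arm]
      list(cytokines = cytl,
           histo = unlist(hc[1, c(pct_cols[1:3], "pyknosis", "discohesion",
                                  "cleaved_caspase3")])[c("tumor_content",
                                                          "immune_content", "infiltration", "pyknosis",
                                                          "discohesion", "cleaved_caspase3")],
           viability = hc$viability_au[1],
           flow = unlist(fl[1, setdiff(names(fl), c("sample_id", "arm"))]),
           counts_column = if (length(col_id)) col_id else NA_character_)
    })
    names(arms) <- arms_here
    cell_list <- lapply(arms_here, function(arm) {
      d <- cells[cells$sample_id == sid & cells$arm == arm,
                 c("x_um", "y_um", "phenotype"), drop = FALSE]
      rownames(d) <- NULL
      d[order(d$phenotype, d$x_um, d$y_um), , drop = FALSE]
    })
    names(cell_list) <- arms_here
    mrow <- meta[meta$sample_id == sid, , drop = FALSE]
    structure(list(sample_id = sid,
                   true_class = mrow$true_class[1] %||% NA_character_,
                   arms = arms, cells = cell_list,
                   metadata = as.list(mrow[1, setdiff(names(mrow),
                                                      c("sample_id", "true_class"))])),
              class = "multimodal_sample")
  })
  structure(samples, class = "multimodal_cohort", counts = cm,
            config = tryCatch(read_run_config(file.path(dir, "config.ini")),
                              error = function(e) NULL))
}

#' Write a fold-change matrix CSV with a metadata header
#'
#' Metadata (aggregation rule, treated arm) is recorded as leading
#' `# key: value` comment lines.
#'
#' @param fcm an `fc_matrix` from [build_fc_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fc_matrix <- function(fcm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s",
                     c("aggregation", "treated_arm", "scale"),
                     c(attr(fcm, "aggregation") %||% "sum_T24_T72",
                       attr(fcm, "treated_arm") %||% "N", "log2")), con)
  df <- data.frame(sample_id = rownames(fcm), as.matrix(unclass(fcm)),
                   check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fold-change matrix CSV written by [write_fc_matrix()]
#' @param path input path.
#' @return an `fc_matrix` (log2 scale, `"linear"` attribute recomputed).
#' @export
read_fc_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    k <- sub(":.*$", "", kv); v <- trimws(sub("^[^:]*:", "", kv))
    meta[[k]] <- v
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^# ", lines)]),
                        check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  attr(m, "linear") <- 2^m
  attr(m, "aggregation") <- meta$aggregation
  attr(m, "treated_arm") <- meta$treated_arm
  class(m) <- c("fc_matrix", class(m))
  m
}

#' Read/write a simple sectioned key = value config file
#'
#' Format: `[section]` headers, `key = value` lines, `#` comments. Values are
#' parsed to numeric or logical where possible; comma-separated values become
#' vectors.
#'
#' @param path file path.
#' @return named list of sections, each a named list of values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_icistrat("config file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(); section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) { section <- gsub("^\\[|\\]$", "", ln); next }
    if (!grepl("=", ln)) stop_icistrat("config parse error at: %s", ln)
    k <- trimws(sub("=.*$", "", ln)); v <- trimws(sub("^[^=]*=", "", ln))
    if (grepl(",", v)) v <- trimws(strsplit(v, ",")[[1]])
    vn <- suppressWarnings(as.numeric(v))
    if (!anyNA(vn)) v <- vn
    else if (all(toupper(v) %in% c("TRUE", "FALSE"))) v <- as.logical(v)
    out[[section]][[k]] <- v
  }
  out
}

#' @rdname read_run_config
#' @param config named list of sections to write.
#' @export
write_run_config <- function(config, path) {
  lines <- character()
  for (sec in names(config)) {
    lines <- c(lines, sprintf("[%s]", sec))
    for (k in names(config[[sec]])) {
      v <- config[[sec]][[k]]
      lines <- c(lines, sprintf("%s = %s", k, paste(format(v, digits = 17, trim = TRUE),
                                                    collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GEO series-matrix-style expression file
#'
#' Tab-delimited file with `!`-prefixed metadata lines and the expression
#' table between `!series_matrix_table_begin` and `!series_matrix_table_end`
#' (first column = gene/probe identifier). Used to score external validation
#' cohorts; metadata lines are returned as an attribute.
#'
#' @param path path to an (uncompressed) series-matrix TSV.
#' @return numeric matrix, genes in rows, with attribute `"metadata"`.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin)
    stop_icistrat("%s: not a series-matrix file (missing table markers)", path)
  meta <- grep("^!", lines[seq_len(begin - 1L)], value = TRUE)
  tab <- utils::read.delim(textConnection(lines[(begin + 1L):(end - 1L)]),
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- gsub('^"|"$', "", tab[[1L]])
  storage.mode(m) <- "double"
  attr(m, "metadata") <- meta
  m
}
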