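#' T0-normalize a cytokine time course
#'
#' Divides each timepoint of a cytokine series (pg/ml at T0, T24, T48, T72) by
#' its pre-treatment T0 value, the standard correction for between-arm
#' differences in functional cell content. The normalized series is 1 at T0
#' whenever T0 > 0.
#'
#' @param values numeric vector of length 4: pg/ml at T0, T24, T48, T72.
#' @param pseudocount non-negative pg/ml added to the T0 denominator; guards
#'   against an undetectable baseline. Default 0.
#' @return numeric vector of length 4 of T0 ratios.
#' @examples
#' t0_normalize(c(50, 100, 150, 200))  # 1 2 3 4
#' @export
t0_normalize <- function(values, pseudocount = 0) {
  stopifnot(is.numeric(values), length(values) == 4L)
  if (any(!is.finite(values)) || any(values < 0))
    stop_icistrat("cytokine values must be finite and >= 0")
  if (pseudocount < 0) stop_icistrat("pseudocount must be >= 0")
  denom <- values[1L] + pseudocount
  if (denom == 0)
    stop_icistrat("undefined baseline: T0 = 0 and pseudocount = 0")
  out <- values / denom
  names(out) <- c("T0", "T24", "T48", "T72")
  out
}

#' Treated-vs-control cytokine fold change
#'
#' Both series are T0-normalized, post-treatment timepoints (T24..T72) are
#' aggregated, and the linear fold change is the treated aggregate over the
#' control aggregate. Media were replenished every 24 h in the assay this
#' models, so the default aggregation sums the three post-treatment ratios
#' (cumulative release); `"T72_only"` uses the endpoint ratio instead.
#'
#' @param treated,control numeric length-4 series (T0, T24, T48, T72), pg/ml.
#' @param aggregation `"sum_T24_T72"` (default) or `"T72_only"`.
#' @param pseudocount passed to [t0_normalize()].
#' @return linear fold change (scalar, > 0 for positive data).
#' @export
cytokine_fold_change <- function(treated, control,
                                 aggregation = c("sum_T24_T72", "T72_only"),
                                 pseudocount = 0) {
  aggregation <- match.arg(aggregation)
  tn <- t0_normalize(treated, pseudocount)
  cn <- t0_normalize(control, pseudocount)
  agg <- function(x) if (aggregation == "sum_T24_T72") sum(x[2:4]) else x[[4L]]
  denom <- agg(cn)
  if (denom == 0) stop_icistrat("undefined fold change: control aggregate is 0")
  unname(agg(tn) / denom)
}

#' Histology fold changes between a treated and the control arm
#'
#' Ratio fold changes for the histopathology response parameters. Tumor
#' content is reported in the cytotoxicity-oriented direction
#' (`control / treated`): a fold change above 1 means the treated arm lost
#' tumor content, so the one rule "FC > 1.2" covers tumor-content decrease
#' alongside the increase-type parameters.
#'
#' @param treated,control named numeric vectors (or one-row lists) with at
#'   least `tumor_content`, `immune_content`, `infiltration`,
#'   `cleaved_caspase3` (all percentages).
#' @return named numeric vector of linear fold changes; tumor content appears
#'   as `tumor_content_cytotox = control/treated`, the rest as
#'   `treated/control`.
#' @export
histo_fold_change <- function(treated, control) {
  treated <- unlist(treated); control <- unlist(control)
  need <- c("tumor_content", "immune_content", "infiltration", "cleaved_caspase3")
  miss <- setdiff(need, intersect(names(treated), names(control)))
  if (length(miss))
    stop_icistrat("missing histology fields: %s", paste(miss, collapse = ", "))
  if (control[["tumor_content"]] <= 0)
    stop_icistrat("undefined: control tumor content is 0")
  if (treated[["tumor_content"]] <= 0)
    stop_icistrat("undefined: treated tumor content is 0")
  ratio <- function(p) {
    if (control[[p]] <= 0) return(NA_real_)
    unname(treated[[p]] / control[[p]])
  }
  c(tumor_content_cytotox = unname(control[["tumor_content"]] / treated[["tumor_content"]]),
    immune_content = ratio("immune_content"),
    infiltration = ratio("infiltration"),
    cleaved_caspase3 = ratio("cleaved_caspase3"))
}

#' Housekeeping-gene normalization of a count matrix
#'
#' nSolver-style content normalization: each column is scaled so the geometric
#' mean of its housekeeping genes equals the cohort-wide mean of those
#' geometric means. `normalized = (raw + pseudocount) * factor`.
#'
#' @param cm a [count_matrix()] with a non-empty housekeeping set (>= 2 genes).
#' @param pseudocount added to raw counts before computing geometric means and
#'   normalized values; default 0.5 so zero counts survive a later log2.
#' @return the `count_matrix` with `$normalized`, `$pseudocount` and a
#'   `"scale_factors"` attribute filled in.
#' @export
normalize_counts <- function(cm, pseudocount = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(cm$housekeeping) < 2L)
    stop_icistrat("need >= 2 housekeeping genes to normalize")
  hk <- cm$counts[cm$housekeeping, , drop = FALSE] + pseudocount
  if (any(hk <= 0))
    stop_icistrat("housekeeping count + pseudocount <= 0; increase pseudocount")
  gm <- apply(hk, 2L, geometric_mean)
  factors <- mean(gm) / gm
  normalized <- sweep(cm$counts + pseudocount, 2L, factors, `*`)
  out <- cm
  out$normalized <- normalized
  out$pseudocount <- pseudocount
  attr(out, "scale_factors") <- factors
  out
}

#' Baseline tumor-content qualification filter
#'
#' Samples whose average tumor content at baseline is below 10% carry too
#' little tumor to read a response from and are excluded from analysis.
#' The threshold is strict: exactly 10% qualifies.
#'
#' @param tumor_content_baseline percentage in `[0, 100]` (vectorized).
#' @return character vector, `"qualified"` or `"non_qualified"`.
#' @export
qc_filter <- function(tumor_content_baseline) {
  if (any(is.na(tumor_content_baseline)))
    stop_icistrat("missing baseline tumor content")
  if (any(tumor_content_baseline < 0 | tumor_content_baseline > 100))
    stop_icistrat("baseline tumor content must be in [0, 100]")
  ifelse(tumor_content_baseline < 10, "non_qualified", "qualified")
}

#' PD-L1 combined positive score
#'
#' `CPS = 100 * (PD-L1 positive cells: tumor cells, lymphocytes, macrophages) /
#' (viable tumor cells)`, capped at 100 per clinical scoring convention.
#'
#' @param n_pdl1_positive count of PD-L1 positive cells.
#' @param n_viable_tumor count of viable tumor cells (> 0).
#' @return CPS in `[0, 100]`.
#' @export
cps_score <- function(n_pdl1_positive, n_viable_tumor) {
  stopifnot(n_pdl1_positive >= 0)
  if (any(n_viable_tumor <= 0))
    stop_icistrat("viable tumor cell count must be > 0")
  pmin(100, 100 * n_pdl1_positive / n_viable_tumor)
}

#' The ten stratification response parameters
#' @return character vector of parameter names in canonical order.
#' @export
fc_parameters <- function() {
  c("IFNg", "IL10", "TNFa", "Perforin", "GranzymeB",
    "tumor_content_cytotox", "immune_content", "infiltration",
    "cleaved_caspase3", "viability")
}

#' Build the 10-parameter fold-change matrix for a cohort
#'
#' For each qualified sample, computes the linear and log2 fold change of the
#' ten stratification parameters of a treated arm versus the control arm: the
#' five response cytokines (IFNg, IL10, TNFa, Perforin, GranzymeB; via
#' [cytokine_fold_change()]), tumor content in the cytotoxicity direction,
#' immune content, immune infiltration, tumor cleaved caspase-3 (via
#' [histo_fold_change()]) and viability fluorescence (treated/control).
#'
#' @param cohort a `multimodal_cohort` from [generate_cohort()] or
#'   [read_cohort()].
#' @param treated_arm arm name to compare against `"Control"`; default `"N"`.
#' @param aggregation cytokine timepoint aggregation, see
#'   [cytokine_fold_change()].
#' @param qc apply [qc_filter()] on baseline (control-arm) tumor content and
#'   drop non-qualified samples. Default `TRUE`.
#' @return object of class `fc_matrix`: a numeric matrix of log2 fold changes
#'   (samples x 10 parameters, rownames = sample ids) with attributes
#'   `linear` (linear-FC matrix), `aggregation`, `treated_arm`, and `dropped`
#'   (samples excluded, with reason).
#' @export
build_fc_matrix <- function(cohort, treated_arm = "N",
                            aggregation = c("sum_T24_T72", "T72_only"),
                            qc = TRUE) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(cohort, "multimodal_cohort"))
  params <- fc_parameters()
  cyto_params <- params[1:5]
  rows <- list(); dropped <- list()
  for (s in cohort) {
    ctl <- s$arms[["Control"]]; trt <- s$arms[[treated_arm]]
    if (is.null(ctl) || is.null(trt)) {
      dropped[[s$sample_id]] <- "missing arm"
      next
    }
    if (qc && qc_filter(ctl$histo[["tumor_content"]]) == "non_qualified") {
      dropped[[s$sample_id]] <- "non_qualified (baseline tumor content < 10%)"
      next
    }
    fc <- rep(NA_real_, length(params)); names(fc) <- params
    ok <- TRUE
    for (p in cyto_params) {
      tv <- trt$cytokines[[p]]; cv <- ctl$cytokines[[p]]
      if (is.null(tv) || is.null(cv)) { ok <- FALSE; break }
      fc[[p]] <- cytokine_fold_change(tv, cv, aggregation)
    }
    if (ok) {
      hf <- histo_fold_change(trt$histo, ctl$histo)
      fc[names(hf)] <- hf
      fc[["viability"]] <- trt$viability / ctl$viability
    }
    if (!ok || any(is.na(fc))) {
      dropped[[s$sample_id]] <- "missing parameter"
      warn_icistrat("sample %s dropped from fold-change matrix: missing parameter",
                    s$sample_id)
      next
    }
    rows[[s$sample_id]] <- fc
  }
  if (!length(rows)) stop_icistrat("no qualified samples with complete parameters")
  linear <- do.call(rbind, rows)
  out <- log2(linear)
  attr(out, "linear") <- linear
  attr(out, "aggregation") <- aggregation
  attr(out, "treated_arm") <- treated_arm
  attr(out, "dropped") <- dropped
  class(out) <- c("fc_matrix", class(out))
  out
}
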