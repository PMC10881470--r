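# End-to-end pipeline and provenance.

#' Digest of an R object (for provenance records)
#'
#' MD5 of the object's version-2 serialization, via a temporary file.
#' @param x any R object.
#' @return hex digest string.
#' @export
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Default pipeline run configuration
#'
#' Every analysis parameter with a stated value in the study this emulates
#' defaults to that value: relevance fold change 1.2 (strict), t-SNE
#' perplexity 10 / learning rate 100 / 1000 iterations, significance level
#' 0.05, PC1 loading threshold 0.7.
#'
#' @param input_dir cohort directory ([write_cohort()] layout); `NULL`
#'   simulates a default cohort with `seed`.
#' @param out_dir output directory.
#' @param treated_arm treated arm for fold changes, default `"N"`.
#' @param aggregation cytokine timepoint aggregation rule.
#' @param relevance_fc phenotype-flag threshold (strict >).
#' @param perplexity,learning_rate,n_iterations t-SNE settings.
#' @param alpha significance level for DE and shift calls.
#' @param loading_threshold PC1 loading threshold.
#' @param region_radius_um tumor-region disk radius, micrometers.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, out_dir = tempfile("icistrat_run_"),
                       treated_arm = "N", aggregation = "sum_T24_T72",
                       relevance_fc = 1.2, perplexity = 10,
                       learning_rate = 100, n_iterations = 1000,
                       alpha = 0.05, loading_threshold = 0.7,
                       region_radius_um = 20, seed = 1L) {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 treated_arm = treated_arm, aggregation = aggregation,
                 relevance_fc = relevance_fc, perplexity = perplexity,
                 learning_rate = learning_rate, n_iterations = n_iterations,
                 alpha = alpha, loading_threshold = loading_threshold,
                 region_radius_um = region_radius_um, seed = as.integer(seed)),
            class = "run_config")
}

sc_columns <- function(cm, labels, sub, arm) {
  ids <- labels$sample_id[labels$sub == sub]
  cm$columns$column_id[cm$columns$sample_id %in% ids & cm$columns$arm == arm]
}

#' Run the full analysis pipeline
#'
#' Stages: read (or simulate) the cohort; baseline QC; 10-parameter
#' fold-change matrix; t-SNE + rule-based sub-cohort stratification;
#' housekeeping normalization; baseline (control-arm SC1 vs SC2d) and
#' on-treatment signature derivation with GES scoring and ROC/Youden;
#' spatial summaries; provenance. All outputs are written to
#' `config$out_dir` and are re-readable by the package's own readers.
#'
#' @param config a [run_config()].
#' @return result bundle (invisible list): `labels`, `fc_matrix`,
#'   `signatures`, `ges`, `roc`, `spatial`, `provenance`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_icistrat("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  warnings_log <- character()
  withCallingHandlers({
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

    cohort <- stage("input", {
      if (is.null(config$input_dir)) generate_cohort(cohort_config(seed = config$seed))
      else read_cohort(config$input_dir)
    })
    cm <- attr(cohort, "counts")

    fcm <- stage("normalization",
                 build_fc_matrix(cohort, treated_arm = config$treated_arm,
                                 aggregation = config$aggregation))
    labels <- stage("stratification",
                    stratify_cohort(fcm,
                                    tsne_params(config$perplexity, config$learning_rate,
                                                config$n_iterations, seed = config$seed),
                                    threshold_config(config$relevance_fc)))
    cm <- stage("count normalization", normalize_counts(cm))

    sigs <- list(); ges <- list(); roc <- NULL
    r_ids <- labels$sample_id[labels$sub == "SC1"]
    nr_ids <- labels$sample_id[labels$sub == "SC2d"]
    base_a <- sc_columns(cm, labels, "SC2d", "Control")
    base_b <- sc_columns(cm, labels, "SC1", "Control")
    trt_a <- sc_columns(cm, labels, "SC2d", config$treated_arm)
    trt_b <- sc_columns(cm, labels, "SC1", config$treated_arm)
    if (length(base_a) >= 2 && length(base_b) >= 2) {
      sigs$baseline <- stage("baseline signature",
                             derive_signature(cm, base_a, base_b, name = "baseline",
                                              alpha = config$alpha,
                                              loading_threshold = config$loading_threshold))
      ges$baseline <- sigs$baseline$scores
      ctl_cols <- cm$columns$arm == "Control"
      sample_of <- cm$columns$sample_id[ctl_cols]
      sc <- ges$baseline[cm$columns$column_id[ctl_cols]]
      lab01 <- ifelse(sample_of %in% r_ids, 1L,
                      ifelse(sample_of %in% nr_ids, 0L, NA_integer_))
      keep <- !is.na(lab01)
      if (any(lab01[keep] == 1) && any(lab01[keep] == 0))
        roc <- stage("roc", roc_youden(sc[keep], lab01[keep]))
    } else {
      warn_icistrat("skipping baseline signature: fewer than 2 SC1 or SC2d samples")
    }
    if (length(trt_a) >= 2 && length(trt_b) >= 2) {
      sigs$on_treatment <- stage("on-treatment signature",
                                 derive_signature(cm, trt_a, trt_b, name = "on_treatment",
                                                  alpha = config$alpha,
                                                  loading_threshold = config$loading_threshold))
      ges$on_treatment <- sigs$on_treatment$scores
    }

    spa <- stage("spatial", {
      cell_rows <- list()
      for (s in cohort)
        for (arm in names(s$cells))
          cell_rows[[paste(s$sample_id, arm)]] <-
            cbind(data.frame(sample_id = s$sample_id, arm = arm), s$cells[[arm]])
      spatial_summary(do.call(rbind, c(cell_rows, make.row.names = FALSE)),
                      r = config$region_radius_um, alpha = config$alpha)
    })

    stage("outputs", {
      write_fc_matrix(fcm, file.path(config$out_dir, "fc_matrix.csv"))
      write_csv_plain(labels, file.path(config$out_dir, "labels.csv"))
      emb <- attr(labels, "embedding")
      write_csv_plain(data.frame(sample_id = rownames(emb), emb),
                      file.path(config$out_dir, "embedding.csv"))
      write_csv_plain(spa, file.path(config$out_dir, "spatial_summary.csv"))
      for (nm in names(sigs)) {
        jsonlite::write_json(
          list(name = sigs[[nm]]$name, genes = sigs[[nm]]$genes,
               derivation = sigs[[nm]]$derivation),
          file.path(config$out_dir, sprintf("signature_%s.json", nm)),
          auto_unbox = TRUE, digits = NA)
        write_csv_plain(data.frame(column_id = names(ges[[nm]]), ges = unname(ges[[nm]])),
                        file.path(config$out_dir, sprintf("ges_%s.csv", nm)))
      }
      if (!is.null(roc))
        jsonlite::write_json(list(auc = roc$auc, youden_cutoff = roc$youden_cutoff,
                                  youden_J = roc$youden_J),
                             file.path(config$out_dir, "roc_baseline.json"),
                             auto_unbox = TRUE, digits = NA)
    })

    prov <- list(
      package_version = as.character(utils::packageVersion("icistrat")),
      config = unclass(config), config_hash = config_hash(unclass(config)),
      seed = config$seed,
      stage_digests = list(fc_matrix = config_hash(unclass(fcm)),
                           labels = config_hash(labels$sub),
                           spatial = config_hash(spa)),
      warnings = warnings_log)
    jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)

    invisible(list(labels = labels, fc_matrix = fcm, signatures = sigs,
                   ges = ges, roc = roc, spatial = spa, provenance = prov))
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}
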