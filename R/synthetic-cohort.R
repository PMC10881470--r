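# Synthetic multimodal cohort generator. The generator states the world the
# analysis assumes: five ground-truth response classes with class-dependent
# multiplicative treatment effects on every modality, multiplicative lognormal
# noise on positive-valued assay readouts, negative-binomial mRNA counts, and
# a minimal spatial mechanism (tumor nest disk + radial CD8/FoxP3 placement
# whose mean shrinks under treatment in responders).

#' Cytokine analytes simulated per arm
#' @return character vector of the 18 analyte names.
#' @export
cytokine_analytes <- function() {
  c("IFNg", "IL10", "TNFa", "Perforin", "GranzymeB",
    "IL1b", "IL2", "MMP9", "CXCL10", "IL6", "CXCL8", "CX3CL1",
    "GCSF", "GMCSF", "CXCL11", "CCL2", "CXCL9", "MCSF")
}

flow_populations <- function() c("CTL", "CD8_Ki67", "CD8_GZMB", "Treg", "M2", "NK")

true_classes <- function() c("R", "M_a", "M_b", "M_c", "NR")

effect_parameters <- function() {
  c(cytokine_analytes(), "tumor_content_cytotox", "immune_content",
    "infiltration", "cleaved_caspase3", "viability", flow_populations())
}

#' Default class-by-parameter treatment effect sizes
#'
#' Mean linear fold changes of the treated (anti-PD1) arm versus control, per
#' ground-truth class. R mirrors the responder phenotype (strong IFNg release,
#' strong cytotoxicity by all four criteria, T-cell homing); M_a moderate
#' reinvigoration plus cytotoxicity; M_b cytotoxicity without reinvigoration;
#' M_c reinvigoration without cytotoxicity; NR neither, with an
#' immunosuppressive flavor (TNFa/IL10/Treg/M2 up). `tumor_content_cytotox`
#' is in the cytotoxicity direction: the treated tumor content is
#' control / effect.
#'
#' @return numeric matrix, classes in rows, parameters in columns.
#' @export
default_effect_sizes <- function() {
  m <- matrix(1, length(true_classes()), length(effect_parameters()),
              dimnames = list(true_classes(), effect_parameters()))
  set <- function(cl, ...) {
    v <- c(...)
    m[cl, names(v)] <<- v
  }
  # R separates strongly on every response axis (the responder sub-cohort sits
  # apart as its own embedding cluster); the four moderate/poor classes share
  # one overlapping moderate cloud and differ only in the flag-relevant
  # parameters, so the embedding shows two distinct clusters, not five.
  set("R", IFNg = 8.0, Perforin = 3.0, GranzymeB = 3.0, CXCL9 = 2.5, CXCL10 = 2.5,
      tumor_content_cytotox = 2.0, immune_content = 1.5, infiltration = 2.0,
      cleaved_caspase3 = 3.0, viability = 0.65,
      CTL = 1.5, CD8_Ki67 = 1.8, CD8_GZMB = 1.8)
  set("M_a", IFNg = 1.6, Perforin = 1.5, GranzymeB = 1.5,
      tumor_content_cytotox = 1.3, cleaved_caspase3 = 1.5,
      CTL = 1.2, CD8_Ki67 = 1.3)
  set("M_b", Perforin = 1.5, GranzymeB = 1.5, tumor_content_cytotox = 1.3,
      cleaved_caspase3 = 1.5)
  set("M_c", IFNg = 1.6)
  set("NR", TNFa = 1.3, IL10 = 1.2, CXCL8 = 1.5, CCL2 = 1.4,
      Treg = 1.5, M2 = 1.3)
  m
}

#' Default spatial generator parameters
#'
#' Tumor nest modeled as one disk; CD8 and FoxP3 cells are placed at
#' exponential radial distances outside the nest boundary. Under treatment the
#' mean CD8 distance shrinks by `homing_shift_um` scaled by the per-class
#' fraction (full homing in R, partial in M_a, none otherwise).
#'
#' @param field_um field-of-view side (micrometers), origin at top-left.
#' @param nest_radius_um tumor nest disk radius.
#' @param n_tumor,n_cd8,n_foxp3,n_other cell counts per phenotype.
#' @param ctl_distance_um mean control-arm CD8 distance from the nest boundary.
#' @param treg_distance_um mean FoxP3 distance from the nest boundary.
#' @param homing_shift_um treatment-induced reduction of the mean CD8
#'   distance (micrometers) at shift fraction 1.
#' @param class_shift_fraction named fractions of the homing shift per class.
#' @return list of spatial parameters.
#' @export
default_spatial_params <- function(field_um = 1000, nest_radius_um = 150,
                                   n_tumor = 300, n_cd8 = 150, n_foxp3 = 60,
                                   n_other = 200, ctl_distance_um = 120,
                                   treg_distance_um = 100, homing_shift_um = 40,
                                   class_shift_fraction = c(R = 1, M_a = 0.5,
                                                            M_b = 0, M_c = 0, NR = 0)) {
  list(field_um = field_um, nest_radius_um = nest_radius_um,
       n_tumor = n_tumor, n_cd8 = n_cd8, n_foxp3 = n_foxp3, n_other = n_other,
       ctl_distance_um = ctl_distance_um, treg_distance_um = treg_distance_um,
       homing_shift_um = homing_shift_um,
       class_shift_fraction = class_shift_fraction)
}

#' Synthetic cohort configuration
#'
#' Defaults state the analysis-set scale of the study this emulates: 55
#' samples in class proportions 9/27/8/5/6 (R, M_a, M_b, M_c, NR), treatment
#' effects from [default_effect_sizes()], 10% multiplicative lognormal assay
#' noise, 750 endogenous + 20 housekeeping genes with negative-binomial
#' counts.
#'
#' @param n_samples cohort size.
#' @param class_proportions named probabilities over
#'   `c("R","M_a","M_b","M_c","NR")`; must sum to 1.
#' @param effect_sizes class-by-parameter matrix of mean linear fold changes
#'   (rows must be known classes; missing parameters default to 1).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise on cytokine/histology/viability/flow readouts (>= 0). 0 switches
#'   all stochastic assay noise off (counts become their expected values).
#' @param n_genes endogenous genes; `n_housekeeping` housekeeping genes.
#' @param n_signature_genes size of each class-responsive gene block (an
#'   immune-activity block elevated in R and an immunosuppression block
#'   elevated in NR).
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param spatial_params see [default_spatial_params()].
#' @param expression_response named per-class multipliers applied to the
#'   immune-activity gene block in treated arms (the on-treatment
#'   transcriptional response); classes absent default to 1.
#' @param arms treatment arms to generate alongside `"Control"`.
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 55,
                          class_proportions = c(R = 9, M_a = 27, M_b = 8,
                                                M_c = 5, NR = 6) / 55,
                          effect_sizes = default_effect_sizes(),
                          noise_cv = 0.1,
                          n_genes = 750, n_housekeeping = 20,
                          n_signature_genes = 20,
                          nb_dispersion = 0.1,
                          spatial_params = default_spatial_params(),
                          expression_response = c(R = 2, M_a = 1.3),
                          arms = c("Control", "N"),
                          seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop_icistrat("class_proportions must sum to 1")
  if (!all(names(class_proportions) %in% true_classes()))
    stop_icistrat("unknown class in class_proportions: %s",
                  paste(setdiff(names(class_proportions), true_classes()), collapse = ", "))
  bad <- setdiff(rownames(effect_sizes), true_classes())
  if (length(bad))
    stop_icistrat("invalid class name in effect_sizes: %s", paste(bad, collapse = ", "))
  if (noise_cv < 0) stop_icistrat("noise_cv must be >= 0")
  stopifnot(n_samples > 0, n_genes > 0, n_housekeeping > 0,
            n_signature_genes > 0, nb_dispersion >= 0)
  if (2 * n_signature_genes > n_genes)
    stop_icistrat("n_genes must hold two disjoint blocks of n_signature_genes")
  if (!"Control" %in% arms) stop_icistrat("arms must include Control")
  # complete the effect matrix over all classes/parameters, default 1
  full <- matrix(1, length(true_classes()), length(effect_parameters()),
                 dimnames = list(true_classes(), effect_parameters()))
  full[rownames(effect_sizes), colnames(effect_sizes)] <- effect_sizes
  structure(list(n_samples = n_samples, class_proportions = class_proportions,
                 effect_sizes = full, noise_cv = noise_cv, n_genes = n_genes,
                 n_housekeeping = n_housekeeping,
                 n_signature_genes = n_signature_genes,
                 nb_dispersion = nb_dispersion, spatial_params = spatial_params,
                 expression_response = expression_response,
                 arms = arms, seed = as.integer(seed)),
            class = "cohort_config")
}

# largest-remainder apportionment of n samples to classes
class_counts <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

noise <- function(cfg, n = 1L) rlnorm_cv(n, cfg$noise_cv)

draw_counts <- function(mu, cfg) {
  if (cfg$noise_cv == 0) return(round(mu))
  if (cfg$nb_dispersion <= 0) return(rpois(length(mu), mu))
  rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
}

# place one sample's cells for every arm; shared raw draws so arms differ
# only through the class/arm-dependent radial means
place_cells <- function(cfg, cls, arms) {
  sp <- cfg$spatial_params
  ctr <- sp$field_um / 2
  clip <- function(v) pmin(pmax(v, 0), sp$field_um)
  # shared architecture draws
  ck_r <- sp$nest_radius_um * sqrt(runif(sp$n_tumor))
  ck_a <- runif(sp$n_tumor, 0, 2 * pi)
  cd8_e <- rexp(sp$n_cd8); cd8_a <- runif(sp$n_cd8, 0, 2 * pi)
  trg_e <- rexp(sp$n_foxp3); trg_a <- runif(sp$n_foxp3, 0, 2 * pi)
  oth_x <- runif(sp$n_other, 0, sp$field_um); oth_y <- runif(sp$n_other, 0, sp$field_um)
  trg_keep <- runif(sp$n_foxp3)
  out <- list()
  for (arm in arms) {
    shift <- if (arm == "Control" || !cls %in% names(sp$class_shift_fraction)) 0
      else sp$homing_shift_um * sp$class_shift_fraction[[cls]]
    mean_cd8 <- max(5, sp$ctl_distance_um - shift)
    mean_trg <- sp$treg_distance_um
    n_trg <- sp$n_foxp3
    if (arm == "N+I" && cls == "M_a") {   # Treg depletion + dispersion
      mean_trg <- sp$treg_distance_um * 1.6
      n_trg <- sum(trg_keep < 0.6)
    }
    keep <- seq_len(sp$n_foxp3) %in% order(trg_keep)[seq_len(n_trg)]
    d_cd8 <- sp$nest_radius_um + mean_cd8 * cd8_e
    d_trg <- sp$nest_radius_um + mean_trg * trg_e[keep]
    cells <- rbind(
      data.frame(x_um = ctr + ck_r * cos(ck_a), y_um = ctr + ck_r * sin(ck_a),
                 phenotype = "panCK"),
      data.frame(x_um = ctr + d_cd8 * cos(cd8_a), y_um = ctr + d_cd8 * sin(cd8_a),
                 phenotype = "CD8"),
      data.frame(x_um = ctr + d_trg * cos(trg_a[keep]),
                 y_um = ctr + d_trg * sin(trg_a[keep]), phenotype = "FoxP3"),
      data.frame(x_um = oth_x, y_um = oth_y, phenotype = "other"))
    cells$x_um <- clip(cells$x_um); cells$y_um <- clip(cells$y_um)
    out[[arm]] <- cells
  }
  out
}

# combination-arm boost on top of the single-agent effects (anti-CTLA4 adds
# Treg depletion and improved cytotoxicity in the moderate responders)
arm_effects <- function(cfg, cls, arm) {
  eff <- cfg$effect_sizes[cls, ]
  if (arm == "Control") { eff[] <- 1; return(eff) }
  if (arm == "N+I" && cls == "M_a") {
    eff[["cleaved_caspase3"]] <- eff[["cleaved_caspase3"]] * 1.5
    eff[["tumor_content_cytotox"]] <- eff[["tumor_content_cytotox"]] * 1.3
    eff[["Perforin"]] <- eff[["Perforin"]] * 1.2
    eff[["IL10"]] <- eff[["IL10"]] * 0.6
    eff[["Treg"]] <- eff[["Treg"]] * 0.6
  }
  eff
}

#' Generate a seeded synthetic multimodal cohort
#'
#' Draws per-sample ground-truth classes (largest-remainder apportionment of
#' the configured proportions, then a seeded shuffle), control-arm baselines,
#' and treated-arm readouts whose expectations equal the control expectations
#' times the class/parameter effect size. Modalities: 18-analyte cytokine
#' time courses (T0, T24, T48, T72), histopathology scores, viability
#' fluorescence, flow-cytometry proportions, a gene-by-column negative
#' binomial count matrix with responsive gene blocks, and per-arm
#' phenotype-labeled cell tables.
#'
#' @param config a [cohort_config()].
#' @return object of class `multimodal_cohort`: a list of `multimodal_sample`
#'   objects with attributes `config`, `counts` (a [count_matrix()]),
#'   `signature_genes` (immune-activity block) and `suppression_genes`
#'   (immunosuppression block).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  with_seed(cfg$seed, {
    ncls <- class_counts(cfg$n_samples, cfg$class_proportions)
    classes <- sample(rep(names(ncls), ncls))
    ids <- sprintf("S%03d", seq_len(cfg$n_samples))
    analytes <- cytokine_analytes()
    shape <- c(1, 1.6, 2.2, 2.8)                  # cumulative release profile
    t0_base <- setNames(rlnorm(length(analytes), log(15), 0.4), analytes)

    genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
    hk <- sprintf("HK%02d", seq_len(cfg$n_housekeeping))
    sig_genes <- genes[seq_len(cfg$n_signature_genes)]
    sup_genes <- genes[cfg$n_signature_genes + seq_len(cfg$n_signature_genes)]
    gene_mu <- setNames(rlnorm(cfg$n_genes, log(150), 1), genes)
    hk_mu <- setNames(rlnorm(cfg$n_housekeeping, log(500), 0.5), hk)

    samples <- vector("list", cfg$n_samples)
    count_cols <- list(); col_meta <- list()
    for (i in seq_len(cfg$n_samples)) {
      cls <- classes[i]
      # shared per-sample baselines (arms are fragments of the same tumor)
      t0 <- t0_base * rlnorm_cv(length(analytes), 0.5)
      histo0 <- c(tumor_content = min(95, rlnorm(1, log(40), 0.3)),
                  immune_content = min(60, rlnorm(1, log(15), 0.4)),
                  infiltration = min(90, rlnorm(1, log(30), 0.4)),
                  cleaved_caspase3 = min(40, rlnorm(1, log(4), 0.5)))
      pyk <- sample(1:3, 1); dis <- sample(1:3, 1)
      viab0 <- rlnorm(1, log(5e4), 0.3)
      flow0 <- c(CTL = 15, CD8_Ki67 = 3, CD8_GZMB = 5, Treg = 4, M2 = 6, NK = 3) *
        rlnorm_cv(length(flow_populations()), 0.3)
      # baseline class flavor: activated CTLs high in R, M2 high in NR,
      # even without treatment
      if (cls == "R") flow0[["CD8_GZMB"]] <- flow0[["CD8_GZMB"]] * 1.5
      if (cls == "NR") flow0[["M2"]] <- flow0[["M2"]] * 1.8
      gmu <- gene_mu
      if (cls == "R") gmu[sig_genes] <- gmu[sig_genes] * 2.5
      if (cls == "M_a") gmu[sig_genes] <- gmu[sig_genes] * 1.5
      if (cls == "NR") gmu[sup_genes] <- gmu[sup_genes] * 2.5

      cells <- place_cells(cfg, cls, cfg$arms)
      arms <- list()
      for (arm in cfg$arms) {
        eff <- arm_effects(cfg, cls, arm)
        cyt <- lapply(analytes, function(a) {
          e <- eff[[a]]
          v <- c(t0[[a]],
                 t0[[a]] * shape[2:4] * e * noise(cfg, 3))
          names(v) <- c("T0", "T24", "T48", "T72")
          v
        })
        names(cyt) <- analytes
        histo <- c(
          tumor_content = min(100, histo0[["tumor_content"]] /
                                eff[["tumor_content_cytotox"]] * noise(cfg)),
          immune_content = min(100, histo0[["immune_content"]] *
                                 eff[["immune_content"]] * noise(cfg)),
          infiltration = min(100, histo0[["infiltration"]] *
                               eff[["infiltration"]] * noise(cfg)),
          pyknosis = pyk, discohesion = dis,
          cleaved_caspase3 = min(100, histo0[["cleaved_caspase3"]] *
                                   eff[["cleaved_caspase3"]] * noise(cfg)))
        flow <- setNames(vapply(flow_populations(), function(p)
          min(100, flow0[[p]] * eff[[p]] * noise(cfg)), 0), flow_populations())
        col_id <- paste0(ids[i], "_", arm)
        # on-treatment transcriptional response of the immune block
        gmu_arm <- gmu
        if (arm != "Control") {
          boost <- if (cls %in% names(cfg$expression_response))
            cfg$expression_response[[cls]] else 1
          gmu_arm[sig_genes] <- gmu_arm[sig_genes] * boost
        }
        lib <- if (cfg$noise_cv == 0) 1 else rlnorm_cv(1, 0.15)
        count_cols[[col_id]] <- c(draw_counts(gmu_arm * lib, cfg),
                                  draw_counts(hk_mu * lib, cfg))
        col_meta[[col_id]] <- data.frame(column_id = col_id, sample_id = ids[i],
                                         arm = arm, stringsAsFactors = FALSE)
        arms[[arm]] <- list(cytokines = cyt, histo = histo,
                            viability = viab0 * eff[["viability"]] * noise(cfg),
                            flow = flow, counts_column = col_id)
      }
      samples[[i]] <- structure(list(
        sample_id = ids[i], true_class = cls, arms = arms, cells = cells,
        metadata = list(grade = sample(1:3, 1, prob = c(.7, .27, .03)),
                        stage = sample(c("I", "II", "III", "IV"), 1,
                                       prob = c(.01, .26, .34, .39)),
                        site = sample(c("buccal mucosa", "tongue", "alveolus",
                                        "lip", "oral cavity"), 1),
                        hpv = sample(c("negative", "positive"), 1, prob = c(.97, .03)),
                        pdl1_cps = round(min(100, rlnorm(1, log(15), 1) + 3)))),
        class = "multimodal_sample")
    }
    counts <- do.call(cbind, count_cols)
    rownames(counts) <- c(genes, hk)
    cm <- count_matrix(counts, housekeeping = hk,
                       columns = do.call(rbind, c(col_meta, make.row.names = FALSE)))
    structure(samples, class = "multimodal_cohort", config = cfg, counts = cm,
              signature_genes = sig_genes, suppression_genes = sup_genes)
  })
}

#' @export
print.multimodal_cohort <- function(x, ...) {
  cls <- table(vapply(x, `[[`, "", "true_class"))
  cat(sprintf("<multimodal_cohort> %d samples (%s); arms: %s\n", length(x),
              paste(names(cls), as.integer(cls), sep = "=", collapse = ", "),
              paste(attr(x, "config")$arms, collapse = ", ")))
  invisible(x)
}

#' Ground-truth classes of a synthetic cohort
#' @param cohort a `multimodal_cohort`.
#' @return named character vector sample id -> class.
#' @export
true_class <- function(cohort) {
  stopifnot(inherits(cohort, "multimodal_cohort"))
  setNames(vapply(cohort, `[[`, "", "true_class"),
           vapply(cohort, `[[`, "", "sample_id"))
}

#' The expected sub-cohort label of each ground-truth class
#' @return named character vector (R -> SC1, ..., NR -> SC2d).
#' @export
class_to_subcohort <- function() {
  c(R = "SC1", M_a = "SC2a", M_b = "SC2b", M_c = "SC2c", NR = "SC2d")
}

#' Simulate survival records from GES scores
#'
#' Event times are exponential with subject hazard
#' `h0 * exp(hazard_slope * (score - mean(score)))`, so a negative slope makes
#' higher scores protective (longer progression-free survival); scores are
#' centered so `baseline_hazard` is the hazard of an average-score subject
#' regardless of the GES scale. Each subject is censored with probability
#' `censor_rate` (uniformly before the event) and administratively at
#' `max_followup`.
#'
#' @param scores finite numeric GES scores.
#' @param hazard_slope slope of the log hazard in the score.
#' @param max_followup administrative censoring time (months).
#' @param censor_rate probability in `[0, 1]` of random early censoring.
#' @param seed integer seed.
#' @param baseline_hazard events per month at score 0, default 0.08.
#' @return data.frame with `id`, `time`, `event`, `score`.
#' @export
generate_survival <- function(scores, hazard_slope = -1, max_followup = 60,
                              censor_rate = 0.2, seed = 1L,
                              baseline_hazard = 0.08) {
  if (any(!is.finite(scores))) stop_icistrat("scores must be finite")
  if (censor_rate < 0 || censor_rate > 1)
    stop_icistrat("censor_rate must be in [0, 1]")
  stopifnot(max_followup > 0, baseline_hazard > 0)
  with_seed(seed, {
    n <- length(scores)
    h <- baseline_hazard * exp(hazard_slope * (scores - mean(scores)))
    e_time <- rexp(n, rate = h)
    early <- runif(n) < censor_rate
    c_time <- ifelse(early, runif(n, 0, pmin(e_time, max_followup)), Inf)
    time <- pmin(e_time, c_time, max_followup)
    event <- as.integer(time == e_time & e_time <= max_followup & !(c_time < e_time))
    time <- pmax(time, 1e-6)
    data.frame(id = sprintf("P%03d", seq_len(n)), time = time,
               event = event, score = scores)
  })
}

#' Replicate-arm equivalence simulation configuration
#'
#' @param n_fragments explant fragments available per simulated tumor.
#' @param replicate_options arm sizes to evaluate (all >= 2).
#' @param fragment_heterogeneity_cv between-fragment coefficient of variation
#'   of tumor content and proliferating-cell content. Default 0.40, a
#'   realistic between-fragment heterogeneity for tumor content.
#' @param n_monte_carlo Monte-Carlo repetitions (>= 1).
#' @param seed integer seed.
#' @return list of class `arm_equivalence_config`.
#' @export
arm_equivalence_config <- function(n_fragments = 40,
                                   replicate_options = c(3, 5, 7, 10),
                                   fragment_heterogeneity_cv = 0.40,
                                   n_monte_carlo = 200, seed = 1L) {
  if (any(replicate_options < 2)) stop_icistrat("replicate_options must all be >= 2")
  if (n_monte_carlo < 1) stop_icistrat("n_monte_carlo must be >= 1")
  if (n_fragments < max(replicate_options) * 2)
    stop_icistrat("n_fragments must be >= 2 * max(replicate_options)")
  structure(list(n_fragments = n_fragments, replicate_options = replicate_options,
                 fragment_heterogeneity_cv = fragment_heterogeneity_cv,
                 n_monte_carlo = n_monte_carlo, seed = as.integer(seed)),
            class = "arm_equivalence_config")
}

#' Simulate across-arm variation versus replicate number
#'
#' Fragments are drawn along the cutting axis with a mild spatial trend plus
#' lognormal between-fragment heterogeneity, then dealt into arms of each
#' candidate size by the round-robin plating strategy (every cross-section
#' represented in every arm). For each replicate count the across-arm CV% of
#' the arm means of tumor content and of proliferating-cell content is
#' computed and averaged over the Monte-Carlo repetitions.
#'
#' @param config an [arm_equivalence_config()].
#' @return data.frame with `replicate_count`, `cv_tumor_content`,
#'   `cv_proliferating` (percent).
#' @export
simulate_arm_equivalence <- function(config) {
  stopifnot(inherits(config, "arm_equivalence_config"))
  cfg <- config
  with_seed(cfg$seed, {
    res <- matrix(0, length(cfg$replicate_options), 2)
    for (mc in seq_len(cfg$n_monte_carlo)) {
      pos <- seq_len(cfg$n_fragments) / cfg$n_fragments
      # gradual drift along the cutting axis, scaled by the heterogeneity so
      # perfectly homogeneous fragments (cv = 0) give exactly zero arm CV
      trend <- exp(0.75 * cfg$fragment_heterogeneity_cv * (pos - 0.5))
      tumor <- 40 * trend * rlnorm_cv(cfg$n_fragments, cfg$fragment_heterogeneity_cv)
      prolif <- 20 * trend * rlnorm_cv(cfg$n_fragments, cfg$fragment_heterogeneity_cv)
      for (k_idx in seq_along(cfg$replicate_options)) {
        k <- cfg$replicate_options[k_idx]
        n_arms <- cfg$n_fragments %/% k
        if (n_arms < 2) stop_icistrat("replicate count %d leaves < 2 arms", k)
        used <- seq_len(n_arms * k)
        arm <- rep(seq_len(n_arms), length.out = length(used))  # round-robin deal
        cv <- function(x) {
          m <- tapply(x[used], arm, mean)
          100 * sd(m) / mean(m)
        }
        res[k_idx, 1] <- res[k_idx, 1] + cv(tumor)
        res[k_idx, 2] <- res[k_idx, 2] + cv(prolif)
      }
    }
    res <- res / cfg$n_monte_carlo
    data.frame(replicate_count = cfg$replicate_options,
               cv_tumor_content = res[, 1], cv_proliferating = res[, 2])
  })
}
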