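test_that("t0_normalize matches the elementwise-division oracle", {
  expect_equal(unname(t0_normalize(c(50, 100, 150, 200))), c(1, 2, 3, 4))
  expect_equal(unname(t0_normalize(c(7, 7, 7, 7))), rep(1, 4))
  with_test_seed(7, {
    for (i in 1:25) {
      v <- runif(4, 0.1, 500)
      expect_equal(unname(t0_normalize(v)), v / v[1], tolerance = 1e-12)
      # scale invariance
      c0 <- runif(1, 0.01, 100)
      expect_equal(t0_normalize(c0 * v), t0_normalize(v), tolerance = 1e-12)
    }
  })
  expect_error(t0_normalize(c(0, 1, 2, 3)), "undefined baseline")
  expect_equal(unname(t0_normalize(c(0, 1, 2, 3), pseudocount = 1)), c(0, 1, 2, 3))
  expect_error(t0_normalize(c(-1, 1, 2, 3)), ">= 0")
})

test_that("cytokine_fold_change matches the explicit formula under both aggregations", {
  x <- c(10, 20, 30, 40)
  expect_equal(cytokine_fold_change(x, x), 1)
  # scaling a whole arm (T0 included) cancels out: T0 normalization at work
  expect_equal(cytokine_fold_change(2 * x, x), 1)
  # treated 2x control at every post-treatment timepoint, equal T0 -> 2
  expect_equal(cytokine_fold_change(c(10, 40, 60, 80), x), 2)
  expect_equal(cytokine_fold_change(c(10, 40, 60, 80), x, "T72_only"), 2)
  with_test_seed(11, {
    for (i in 1:25) {
      tr <- runif(4, 1, 100); ct <- runif(4, 1, 100)
      expect_equal(cytokine_fold_change(tr, ct),
                   sum(tr[2:4] / tr[1]) / sum(ct[2:4] / ct[1]),
                   tolerance = 1e-12)
      expect_equal(cytokine_fold_change(tr, ct, "T72_only"),
                   (tr[4] / tr[1]) / (ct[4] / ct[1]), tolerance = 1e-12)
    }
  })
})

test_that("histo_fold_change has the cytotoxicity orientation for tumor content", {
  ctl <- c(tumor_content = 40, immune_content = 10, infiltration = 20,
           cleaved_caspase3 = 5)
  trt <- c(tumor_content = 20, immune_content = 15, infiltration = 30,
           cleaved_caspase3 = 10)
  fc <- histo_fold_change(trt, ctl)
  expect_equal(fc[["tumor_content_cytotox"]], 2)   # halved content, FC > 1
  expect_equal(fc[["cleaved_caspase3"]], 2)
  expect_equal(unname(histo_fold_change(ctl, ctl)), rep(1, 4))
  with_test_seed(3, {
    for (i in 1:20) {
      a <- ctl * runif(4, 0.5, 2); b <- ctl * runif(4, 0.5, 2)
      fc <- histo_fold_change(a, b)
      expect_equal(fc[["tumor_content_cytotox"]],
                   b[["tumor_content"]] / a[["tumor_content"]], tolerance = 1e-12)
      expect_equal(fc[["immune_content"]],
                   a[["immune_content"]] / b[["immune_content"]], tolerance = 1e-12)
    }
  })
  expect_error(histo_fold_change(trt, replace(ctl, 1, 0)), "control tumor content")
})

test_that("normalize_counts equalizes housekeeping geometric means", {
  cm <- toy_count_matrix()
  out <- normalize_counts(cm)
  hk <- out$normalized[out$housekeeping, ]
  gm <- apply(hk, 2, function(x) exp(mean(log(x))))
  expect_lt(diff(range(gm)), 1e-9)
  # identical columns -> all factors 1
  m <- cm$counts[, c(1, 1, 1)]
  colnames(m) <- sprintf("X%d_Control", 1:3)
  same <- normalize_counts(count_matrix(m, cm$housekeeping))
  expect_equal(unname(attr(same, "scale_factors")), rep(1, 3), tolerance = 1e-12)
  # one column doubled (pseudocount 0 keeps the rescaling exact)
  x <- cm$counts[, 1] + 1
  m2 <- cbind(x, 2 * x)
  colnames(m2) <- c("A_Control", "B_Control")
  dbl <- normalize_counts(count_matrix(m2, cm$housekeeping), pseudocount = 0)
  f <- attr(dbl, "scale_factors")
  expect_equal(unname(f[2] / f[1]), 0.5, tolerance = 1e-12)
  expect_equal(dbl$normalized[, 1], dbl$normalized[, 2], tolerance = 1e-12)
  # idempotency: renormalizing an already-normalized matrix gives factors 1
  renorm <- normalize_counts(count_matrix(out$normalized, out$housekeeping),
                             pseudocount = 0)
  expect_equal(unname(attr(renorm, "scale_factors")), rep(1, ncol(out$counts)),
               tolerance = 1e-9)
  expect_error(normalize_counts(count_matrix(m, character())), "housekeeping")
})

test_that("qc_filter applies the strict 10% baseline rule", {
  expect_equal(qc_filter(9.9), "non_qualified")
  expect_equal(qc_filter(10), "qualified")
  expect_equal(qc_filter(85), "qualified")
  expect_equal(qc_filter(c(0, 9.999, 10.001)),
               c("non_qualified", "non_qualified", "qualified"))
  expect_error(qc_filter(NA), "missing")
  expect_error(qc_filter(101), "\\[0, 100\\]")
})

test_that("cps_score follows the formula and caps at 100", {
  expect_equal(cps_score(20, 100), 20)
  expect_equal(cps_score(0, 50), 0)
  expect_equal(cps_score(200, 100), 100)
  expect_error(cps_score(5, 0), "> 0")
})

test_that("build_fc_matrix reproduces per-parameter oracle fold changes", {
  null_cfg <- cohort_config(
    n_samples = 8, noise_cv = 0,
    effect_sizes = matrix(1, 5, length(icistrat::fc_parameters()),
                          dimnames = list(c("R", "M_a", "M_b", "M_c", "NR"),
                                          icistrat::fc_parameters())),
    spatial_params = default_spatial_params(homing_shift_um = 0),
    expression_response = c(), seed = 5)
  fcm <- build_fc_matrix(generate_cohort(null_cfg))
  expect_equal(max(abs(fcm)), 0, tolerance = 1e-12)   # null effect -> log2 FC 0

  coh <- generate_cohort(cohort_config(n_samples = 12, seed = 9))
  fcm <- build_fc_matrix(coh)
  expect_identical(colnames(fcm), fc_parameters())
  linear <- attr(fcm, "linear")
  expect_equal(unclass(fcm), log2(linear), tolerance = 1e-12,
               ignore_attr = TRUE)
  # recompute one sample's parameters directly from the raw readouts
  s <- coh[[which(vapply(coh, `[[`, "", "sample_id") == rownames(fcm)[1])]]
  ctl <- s$arms$Control; trt <- s$arms$N
  expect_equal(linear[1, "IFNg"],
               cytokine_fold_change(trt$cytokines$IFNg, ctl$cytokines$IFNg),
               tolerance = 1e-12)
  expect_equal(linear[1, "tumor_content_cytotox"],
               ctl$histo[["tumor_content"]] / trt$histo[["tumor_content"]],
               tolerance = 1e-12)
  expect_equal(linear[1, "viability"], trt$viability / ctl$viability,
               tolerance = 1e-12)
})

test_that("noiseless IFNg effect 4 gives log2 FC exactly 2", {
  eff <- default_effect_sizes()
  eff["R", "IFNg"] <- 4
  cfg <- one_class_config("R", seed = 2, n_samples = 3, noise_cv = 0,
                          effect_sizes = eff)
  fcm <- build_fc_matrix(generate_cohort(cfg))
  expect_equal(unname(fcm[, "IFNg"]), rep(2, 3), tolerance = 1e-12)
})
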