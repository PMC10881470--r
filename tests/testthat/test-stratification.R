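test_that("assign_subcohort truth table is total and matches the definitions", {
  grid <- expand.grid(primary = c("SC1", "SC2"), reinv = c(TRUE, FALSE),
                      cyto = c(TRUE, FALSE), stringsAsFactors = FALSE)
  got <- assign_subcohort(grid$primary, grid$reinv, grid$cyto)
  want <- ifelse(grid$primary == "SC1", "SC1",
                 ifelse(grid$reinv & grid$cyto, "SC2a",
                        ifelse(!grid$reinv & grid$cyto, "SC2b",
                               ifelse(grid$reinv, "SC2c", "SC2d"))))
  expect_identical(got, want)
  expect_identical(sort(unique(got)), c("SC1", "SC2a", "SC2b", "SC2c", "SC2d"))
})

test_that("phenotype flags use strict > 1.2 with OR over cytotoxicity criteria", {
  base <- c(IFNg = 1, tumor_content_cytotox = 1, cleaved_caspase3 = 1,
            Perforin = 1, GranzymeB = 1)
  f <- phenotype_flags(base)
  expect_false(f$reinvigoration); expect_false(f$cytotoxicity)
  # exactly 1.2 is NOT a relevant change
  f <- phenotype_flags(replace(base, "IFNg", 1.2))
  expect_false(f$reinvigoration)
  f <- phenotype_flags(replace(base, "Perforin", 1.2))
  expect_false(f$cytotoxicity)
  f <- phenotype_flags(c(IFNg = 1.0, Perforin = 1.5, tumor_content_cytotox = 1,
                         cleaved_caspase3 = 1, GranzymeB = 1))
  expect_false(f$reinvigoration); expect_true(f$cytotoxicity)  # SC2b pattern
  for (p in c("tumor_content_cytotox", "cleaved_caspase3", "Perforin", "GranzymeB")) {
    f <- phenotype_flags(replace(base, p, 1.21))
    expect_true(f$cytotoxicity)
  }
  expect_error(phenotype_flags(c(IFNg = 2)), "cytotoxicity")
  expect_error(phenotype_flags(c(Perforin = 2)), "IFNg")
  # monotonicity: lowering the threshold never turns a true flag false
  with_test_seed(4, {
    for (i in 1:40) {
      fc <- setNames(exp(rnorm(5, 0, 0.4)), names(base))
      hi <- phenotype_flags(fc, threshold_config(1.3))
      lo <- phenotype_flags(fc, threshold_config(1.05))
      expect_true(!hi$reinvigoration || lo$reinvigoration)
      expect_true(!hi$cytotoxicity || lo$cytotoxicity)
    }
  })
  expect_error(threshold_config(1), "> 1")
})

test_that("embed_tsne is seeded-deterministic and errors as specified", {
  with_test_seed(1, {
    X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(sprintf("S%02d", 1:30), NULL))
  })
  p <- tsne_params(perplexity = 5, n_iterations = 300, seed = 7)
  e1 <- embed_tsne(X, p)
  e2 <- embed_tsne(X, p)
  expect_identical(e1, e2)
  expect_error(embed_tsne(X[1:5, ], p), "perplexity")
  Xna <- X; Xna[3, 2] <- NA
  expect_error(embed_tsne(Xna, p), "S03")
  expect_error(tsne_params(n_iterations = 100), ">= 250")
})

test_that("embedding preserves separation of two well-separated blobs", {
  with_test_seed(21, {
    centers <- rbind(rep(0, 10), rep(6 / sqrt(10), 10))
    lab <- rep(1:2, each = 25)
    X <- centers[lab, ] + matrix(rnorm(50 * 10, sd = 0.1), 50, 10)
    rownames(X) <- sprintf("S%02d", 1:50)
  })
  emb <- embed_tsne(X, tsne_params(seed = 3, n_iterations = 500))
  # mean silhouette of the true 2-cluster labeling in the embedding
  D <- as.matrix(dist(emb))
  sil <- vapply(1:50, function(i) {
    a <- mean(D[i, lab == lab[i] & seq_len(50) != i])
    b <- mean(D[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.6)
})

test_that("split_primary recovers a separable responder class and is permutation-invariant", {
  cfg <- cohort_config(seed = 31, noise_cv = 0)
  coh <- generate_cohort(cfg)
  fcm <- build_fc_matrix(coh)
  pri <- split_primary(embed_tsne(fcm, tsne_params(seed = 31)), fcm)
  tc <- true_class(coh)[names(pri)]
  expect_identical(unname(pri == "SC1"), unname(tc == "R"))
  # permutation of sample order changes nothing
  perm <- with_test_seed(5, sample(nrow(fcm)))
  fcm_p <- fcm[perm, ]
  attr(fcm_p, "linear") <- attr(fcm, "linear")[perm, ]
  class(fcm_p) <- class(fcm)
  pri_p <- split_primary(embed_tsne(fcm_p, tsne_params(seed = 31)), fcm_p)
  expect_identical(pri_p[names(pri)], pri)
  # degenerate embedding errors; low separation warns
  expect_error(split_primary(matrix(1, 10, 2), fcm[1:10, ]), "degenerate")
  with_test_seed(8, {
    one_blob <- matrix(rnorm(40), 20, 2)
    fcm_one <- matrix(rnorm(200), 20, 10,
                      dimnames = list(sprintf("S%d", 1:20), fc_parameters()))
  })
  expect_warning(split_primary(one_blob, fcm_one), "low separation")
})

test_that("compare_groups matches brute-force enumeration and wilcox.test", {
  # identical paired vectors -> p = 1 with warning
  expect_warning(res <- compare_groups(1:5, 1:5, paired = TRUE), "zero")
  expect_equal(res$p, 1)
  # spec example: paired differences (1,2,3,4,5), all 2^5 sign patterns
  a <- c(2, 4, 6, 8, 10); b <- c(1, 2, 3, 4, 5)
  res <- compare_groups(a, b, paired = TRUE)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
  wplus <- apply(signs, 1, function(s) sum(rank(1:5)[s > 0]))
  p_oracle <- min(1, 2 * min(mean(wplus <= res$statistic),
                             mean(wplus >= res$statistic)))
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  # against stats::wilcox.test (exact, no ties), paired and unpaired
  with_test_seed(13, {
    for (i in 1:20) {
      x <- rnorm(8); y <- rnorm(9)
      expect_equal(compare_groups(x, y)$p,
                   wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
      x2 <- rnorm(7); y2 <- rnorm(7)
      expect_equal(compare_groups(x2, y2, paired = TRUE)$p,
                   wilcox.test(x2, y2, paired = TRUE, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
  expect_error(compare_groups(1:2, 1:5, paired = TRUE), "equal lengths")
  expect_error(compare_groups(1:2, 3:4), "n >= 3")
})

test_that("compare_groups holds its type-I error at large n (normal branch)", {
  with_test_seed(17, {
    n_sim <- 600
    rej <- mean(replicate(n_sim, {
      compare_groups(rnorm(30), rnorm(30))$p < 0.05
    }))
    expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim))
  })
})

test_that("full stratification labels SC2 samples by their flags", {
  coh <- generate_cohort(cohort_config(seed = 41))
  fcm <- build_fc_matrix(coh)
  lab <- stratify_cohort(fcm, tsne_params(seed = 41))
  linear <- attr(fcm, "linear")
  for (i in seq_len(nrow(lab))) {
    if (lab$primary[i] == "SC1") next
    fl <- phenotype_flags(linear[lab$sample_id[i], ])
    expect_identical(lab$sub[i],
                     assign_subcohort("SC2", fl$reinvigoration, fl$cytotoxicity))
  }
})
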