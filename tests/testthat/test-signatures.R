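test_that("differential_expression recovers exact fold changes and degenerate cases", {
  m <- matrix(c(10, 10, 10, 10, 20, 20, 20, 20,
                50, 50, 50, 50, 50, 50, 50, 50), 2, 8, byrow = TRUE,
              dimnames = list(c("g_double", "g_flat"),
                              sprintf("C%d_Control", 1:8)))
  cm <- count_matrix(m)
  de <- suppressWarnings(
    differential_expression(cm, colnames(m)[1:4], colnames(m)[5:8], pseudocount = 0))
  expect_equal(de$log2fc[de$gene == "g_double"], 1)     # exact doubling
  expect_equal(de$log2fc[de$gene == "g_flat"], 0)
  expect_equal(de$p[de$gene == "g_flat"], 1)            # identical groups
  expect_equal(de$p[de$gene == "g_double"], 0)          # zero residual variance
  expect_error(differential_expression(cm, colnames(m)[1], colnames(m)[2:4]),
               ">= 2 columns")
})

test_that("select_significant uses a strict unadjusted threshold", {
  de <- data.frame(gene = c("a", "b", "c"), p = c(0.04, 0.05, 0.06))
  expect_identical(select_significant(de), "a")
  expect_identical(select_significant(data.frame(gene = "x", p = 0.5)), character(0))
  with_test_seed(2, {
    de <- data.frame(gene = sprintf("g%03d", 1:200), p = runif(200))
    expect_identical(select_significant(de, 0.1), de$gene[de$p < 0.1])
  })
})

test_that("pca_loading_select matches brute-force eigendecomposition", {
  # rank-1 structure: all genes perfectly correlated -> |loading| = 1
  with_test_seed(5, {
    f <- rnorm(12)
    expr1 <- outer(c(1, -2, 3, 0.5), f)  # 4 genes, 12 samples
    rownames(expr1) <- sprintf("g%d", 1:4)
    sel <- pca_loading_select(expr1)
    expect_equal(unname(abs(sel$loadings)), rep(1, 4), tolerance = 1e-9)
    expect_identical(sel$genes, rownames(expr1))
    expect_equal(unname(sel$explained["PC1"]), 1, tolerance = 1e-9)
  })
  # oracle: loadings = eigenvector * sqrt(eigenvalue) of the gene correlation matrix
  with_test_seed(6, {
    expr <- matrix(rnorm(8 * 15), 8, 15, dimnames = list(sprintf("g%d", 1:8), NULL))
    sel <- pca_loading_select(expr, loading_threshold = 0.3)
    R <- cor(t(expr))
    ei <- eigen(R)
    # prcomp divides by n-1, so its eigenvalues are those of the correlation matrix
    oracle2 <- ei$vectors[, 1] * sqrt(ei$values[1])
    expect_equal(abs(unname(sel$loadings)), abs(oracle2), tolerance = 1e-9)
    expect_setequal(sel$genes, rownames(expr)[abs(oracle2) > 0.3])
  })
  # white-noise genes with many samples rarely pass 0.7
  with_test_seed(7, {
    expr <- matrix(rnorm(20 * 200), 20, 200, dimnames = list(sprintf("g%d", 1:20), NULL))
    sel <- pca_loading_select(expr, 0.7)
    expect_lte(length(sel$genes), 1)
  })
  expect_warning(pca_loading_select(rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4),
                                          c = c(4, 3, 2, 1))), "constant")
})

test_that("intersect_with_panel is case-insensitive, order-preserving, deduplicating", {
  expect_identical(intersect_with_panel(c("A", "B", "C"), c("B", "C", "D")),
                   c("B", "C"))
  expect_warning(out <- intersect_with_panel(c("A", "B"), c("X", "Y")), "no overlap")
  expect_length(out, 0)
  expect_identical(intersect_with_panel(c("ifng", "IFNG", "Gzmb"), c("IFNg", "GZMB")),
                   c("ifng", "Gzmb"))
  expect_error(intersect_with_panel(character(), "A"), "non-empty")
})

test_that("ges_score is the mean of log2 counts and is monotone", {
  m <- matrix(c(4, 16), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(ges_score(m, c("g1", "g2"))), 3)
  with_test_seed(8, {
    m <- matrix(rnbinom(50 * 6, mu = 100, size = 5) + 1, 50, 6,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
    genes <- sprintf("g%02d", 1:10)
    expect_equal(ges_score(m, genes), colMeans(log2(m[genes, ])), tolerance = 1e-12)
    expect_equal(ges_score(2 * m, genes), ges_score(m, genes) + 1, tolerance = 1e-12)
    # monotone in any signature gene's count
    m2 <- m; m2["g03", 2] <- m2["g03", 2] + 50
    expect_gt(ges_score(m2, genes)[2], ges_score(m, genes)[2])
  })
  expect_error(ges_score(m, c("g1", "missing")), "missing")
})

test_that("zscore_matrix centers and scales rows (sample SD)", {
  expect_equal(unname(zscore_matrix(matrix(c(1, 2, 3), 1))), matrix(c(-1, 0, 1), 1))
  expect_warning(z <- zscore_matrix(matrix(c(5, 5, 5), 1)), "zero-variance")
  expect_equal(unname(z), matrix(0, 1, 3))
  with_test_seed(9, {
    m <- matrix(rnorm(60), 6, 10)
    z <- zscore_matrix(m)
    expect_equal(unname(apply(z, 1, mean)), rep(0, 6), tolerance = 1e-12)
    expect_equal(unname(apply(z, 1, sd)), rep(1, 6), tolerance = 1e-12)
  })
})

test_that("hierarchical_cluster merges duplicates first and matches dist oracle", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  hc <- hierarchical_cluster(m, "rows")
  expect_equal(hc$hclust$height[1], 0)
  m2 <- rbind(a = 0, b = 1, c = 10)
  hc2 <- hierarchical_cluster(m2, "rows")
  first <- sort(abs(hc2$hclust$merge[1, ]))
  expect_equal(first, c(1, 2))                    # (0,1) merge precedes 10
  with_test_seed(10, {
    m3 <- matrix(rnorm(40), 8, 5)
    expect_equal(as.vector(dist(m3)),
                 as.vector(sqrt(as.dist(outer(1:8, 1:8, Vectorize(function(i, j)
                   sum((m3[i, ] - m3[j, ])^2)))))), tolerance = 1e-12)
    hc3 <- hierarchical_cluster(m3, "cols")
    expect_setequal(hc3$order, 1:5)
  })
})

test_that("spearman_correlate matches cor.test and handles monotone/constant cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_correlate(x, x^3)$rho, 1)
  expect_equal(spearman_correlate(x, -x)$rho, -1)
  with_test_seed(12, {
    for (i in 1:10) {
      a <- rnorm(6); b <- rnorm(6)
      res <- spearman_correlate(a, b)
      ct <- cor.test(a, b, method = "spearman", exact = TRUE)
      expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(res$p, ct$p.value, tolerance = 1e-12)
    }
    # t-approximation branch
    a <- rnorm(40); b <- a + rnorm(40)
    res <- spearman_correlate(a, b)
    ct <- cor.test(a, b, method = "spearman", exact = FALSE, continuity = FALSE)
    expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-3)
  })
  expect_warning(res <- spearman_correlate(rep(1, 6), 1:6), "constant")
  expect_true(is.na(res$rho))
  expect_error(spearman_correlate(1:3, 1:3), "n >= 4")
})

test_that("derive_signature chains DE, loading selection and panel overlap", {
  d <- nb_group_matrix(120, 8, 8, planted = 1:15, effect = 3, seed = 3)
  sig <- derive_signature(d$cm, d$group_a, d$group_b, name = "test")
  expect_s3_class(sig, "gene_signature")
  expect_gt(length(intersect(sig$genes, d$genes[1:15])), 10)
  expect_equal(length(sig$scores), 16)
  panel <- c(d$genes[1:5], "OTHER1")
  sig2 <- derive_signature(d$cm, d$group_a, d$group_b, panel = panel)
  expect_true(all(sig2$genes %in% d$genes[1:5]))
})
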