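#' Per-gene differential expression between two column groups
#'
#' Simplified Wald differential expression on housekeeping-normalized counts:
#' for each gene, ordinary least squares of `log2(normalized + pseudocount)`
#' on a group indicator (B vs A). The Wald statistic is the group coefficient
#' over its standard error, with a two-sided p from the t distribution with
#' n - 2 degrees of freedom. This stands in for the unpublished model of the
#' vendor software used upstream of the original gene lists; no multiple
#' testing correction is applied (signature filtering is at unadjusted
#' p < 0.05 downstream).
#'
#' @param cm a [count_matrix()]; normalized counts are used when present,
#'   raw counts otherwise.
#' @param group_a,group_b column ids of the two groups (>= 2 each).
#' @param pseudocount added before log2 when the matrix carries no
#'   normalization pseudocount of its own; default 0.5.
#' @return data.frame of class `de_result`: `gene`, `log2fc` (B vs A),
#'   `wald`, `p`.
#' @export
differential_expression <- function(cm, group_a, group_b, pseudocount = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  vals <- expr_values(cm)
  miss <- setdiff(c(group_a, group_b), colnames(vals))
  if (length(miss)) stop_icistrat("unknown columns: %s", paste(miss, collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_icistrat("need >= 2 columns per group")
  pc <- if (!is.null(cm$normalized) && is.finite(cm$pseudocount)) 0 else pseudocount
  y <- log2(vals[, c(group_a, group_b), drop = FALSE] + pc)
  x <- c(rep(0, length(group_a)), rep(1, length(group_b)))
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  beta <- as.vector(y %*% xc) / sxx
  fitted_resid2 <- rowSums((y - rowMeans(y) - outer(beta, xc))^2)
  s2 <- fitted_resid2 / (n - 2)
  se <- sqrt(s2 / sxx)
  wald <- beta / se
  p <- 2 * pt(-abs(wald), df = n - 2)
  zero_var <- s2 <= 1e-24
  if (any(zero_var)) {
    warn_icistrat("%d gene(s) with zero residual variance", sum(zero_var))
    p[zero_var] <- ifelse(abs(beta[zero_var]) > 1e-12, 0, 1)
    wald[zero_var] <- ifelse(abs(beta[zero_var]) > 1e-12, Inf, 0) * sign(beta[zero_var] + 1e-300)
  }
  structure(data.frame(gene = rownames(vals), log2fc = beta, wald = wald, p = p,
                       stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}

#' Filter a DE result to significant genes
#'
#' Strict unadjusted threshold `p < alpha`, input order preserved.
#'
#' @param de a `de_result` from [differential_expression()].
#' @param alpha significance level, default 0.05.
#' @return character vector of gene ids.
#' @export
select_significant <- function(de, alpha = 0.05) {
  stopifnot(is.data.frame(de), all(c("gene", "p") %in% names(de)))
  de$gene[!is.na(de$p) & de$p < alpha]
}

#' Select genes by absolute PC1 loading
#'
#' PCA on gene-standardized data with genes as variables (samples as
#' observations). Loadings are eigenvector entries scaled by the square root
#' of the eigenvalue, i.e. the correlation of each gene with the component
#' score, bounded in \[-1, 1\]. The orientation of a principal component is
#' arbitrary, so two selection modes exist: without `orient`, genes whose
#' *absolute* PC1 loading exceeds the threshold are returned; with `orient`
#' (a per-sample covariate such as a responder indicator), PC1 is first
#' flipped so its sample scores correlate positively with `orient` and genes
#' with *signed* loading above the threshold are returned. The signed mode is
#' what a plain-average expression signature needs: genes anti-correlated
#' with the component (e.g. immunosuppression genes high in non-responders)
#' would otherwise cancel the signature mean.
#'
#' @param expr numeric matrix of log2 expression, genes in rows, samples in
#'   columns (restricted to e.g. the significant genes).
#' @param loading_threshold strict threshold on the PC1 loading; default 0.7.
#' @param orient optional numeric vector, one value per sample, fixing the
#'   component orientation.
#' @return list with `genes` (selected ids), `loadings` (named PC1 loadings,
#'   oriented when `orient` is given), and `explained` (variance fractions
#'   for PC1 and PC2).
#' @export
pca_loading_select <- function(expr, loading_threshold = 0.7, orient = NULL) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L || ncol(expr) < 3L)
    stop_icistrat("need >= 2 genes and >= 3 samples")
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0)) {
    warn_icistrat("excluding %d constant gene(s) before PCA", sum(sds == 0))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  X <- t(scale(t(expr)))              # standardize each gene
  pca <- prcomp(t(X), center = FALSE, scale. = FALSE)
  ev <- pca$sdev^2
  # loading = eigenvector * sqrt(eigenvalue), rescaled to the correlation
  # scale of the standardized variables (sample variance convention)
  load1 <- pca$rotation[, 1L] * pca$sdev[1L]
  names(load1) <- rownames(expr)
  explained <- ev / sum(ev)
  if (is.null(orient)) {
    sel <- names(load1)[abs(load1) > loading_threshold]
  } else {
    stopifnot(length(orient) == ncol(expr))
    flip <- cor(pca$x[, 1L], orient)
    if (is.finite(flip) && flip < 0) load1 <- -load1
    sel <- names(load1)[load1 > loading_threshold]
  }
  list(genes = sel, loadings = load1,
       explained = c(PC1 = explained[1L], PC2 = if (length(explained) > 1L) explained[2L] else NA_real_))
}

#' Intersect a derived gene list with a clinical panel
#'
#' Case-insensitive symbol intersection preserving first-list order.
#' Duplicates are removed before intersecting; symbol alias mapping is the
#' caller's responsibility.
#'
#' @param genes derived gene list (character).
#' @param panel panel gene list (character).
#' @return character vector (spelling of `genes`), possibly empty (warning).
#' @export
intersect_with_panel <- function(genes, panel) {
  if (!length(genes) || !length(panel)) stop_icistrat("both gene lists must be non-empty")
  genes <- genes[!duplicated(toupper(genes))]
  out <- genes[toupper(genes) %in% unique(toupper(panel))]
  if (!length(out)) warn_icistrat("no overlap between gene list and panel")
  out
}

#' Gene expression signature (GES) score
#'
#' GES of a column is the mean over the signature genes of
#' `log2(normalized count + pseudocount)`.
#'
#' @param cm a [count_matrix()] (normalized counts used when present) or a
#'   plain numeric matrix with gene rownames.
#' @param genes signature gene ids; all must be present.
#' @param pseudocount added inside the log2; default 0 (normalized counts are
#'   already strictly positive).
#' @return named numeric vector of per-column scores.
#' @examples
#' m <- matrix(c(4, 16), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' ges_score(m, c("g1", "g2"))  # 3
#' @export
ges_score <- function(cm, genes, pseudocount = 0) {
  vals <- if (inherits(cm, "count_matrix")) expr_values(cm) else as.matrix(cm)
  miss <- setdiff(genes, rownames(vals))
  if (length(miss))
    stop_icistrat("signature genes absent from matrix: %s", paste(miss, collapse = ", "))
  colMeans(log2(vals[genes, , drop = FALSE] + pseudocount))
}

#' Row-wise z-score a matrix
#'
#' Each row is centered and scaled to unit standard deviation (sample SD,
#' n - 1 denominator, matching `scale()`); used for fold-change heatmaps.
#' Zero-variance rows become zeros with a warning.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape.
#' @export
zscore_matrix <- function(m) {
  m <- as.matrix(m)
  out <- t(apply(m, 1L, function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }))
  zero <- apply(m, 1L, function(x) isTRUE(sd(x) == 0))
  if (any(zero)) warn_icistrat("%d zero-variance row(s) z-scored to 0", sum(zero))
  dimnames(out) <- dimnames(m)
  out
}

#' Euclidean hierarchical clustering with deterministic leaf order
#'
#' Agglomerative clustering (average linkage) on Euclidean distances along the
#' requested axis; ties resolve by input index via the deterministic behavior
#' of `stats::hclust`.
#'
#' @param m numeric matrix.
#' @param axis `"rows"` or `"cols"`.
#' @return list with `hclust` (the tree) and `order` (leaf indices).
#' @export
hierarchical_cluster <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  if (axis == "cols") m <- t(m)
  if (nrow(m) < 2L) stop_icistrat("need >= 2 items to cluster")
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  list(hclust = hc, order = hc$order)
}

#' Derive a gene expression signature from a count matrix
#'
#' The full signature chain: differential expression between two groups,
#' strict `p < alpha` filter, PCA |PC1 loading| > threshold selection and,
#' optionally, case-insensitive intersection with a clinical panel gene list.
#' GES scores for all columns of the matrix are attached.
#'
#' @param cm a normalized [count_matrix()].
#' @param group_a,group_b column ids (e.g. SC1 vs SC2d columns).
#' @param panel optional character vector of panel genes to intersect with.
#' @param name signature name for provenance.
#' @param alpha DE significance level (default 0.05).
#' @param loading_threshold PC1 loading threshold (default 0.7).
#' @return object of class `gene_signature`: list with `name`, `genes`,
#'   `derivation` (parameters, per-stage gene counts, PCA variance fractions)
#'   and `scores` (per-column GES).
#' @export
derive_signature <- function(cm, group_a, group_b, panel = NULL,
                             name = "signature", alpha = 0.05,
                             loading_threshold = 0.7) {
  de <- differential_expression(cm, group_a, group_b)
  sig_genes <- select_significant(de, alpha)
  if (length(sig_genes) < 2L)
    stop_icistrat("fewer than 2 significant genes at alpha = %g", alpha)
  vals <- expr_values(cm)
  expr <- log2(vals[sig_genes, c(group_a, group_b), drop = FALSE] +
                 if (!is.null(cm$normalized)) 0 else 0.5)
  # orient PC1 toward group B (responders): the GES is a plain average, so
  # only concordant (responder-up) genes enter the signature
  pca <- pca_loading_select(expr, loading_threshold,
                            orient = c(rep(0, length(group_a)),
                                       rep(1, length(group_b))))
  genes <- pca$genes
  n_before_panel <- length(genes)
  if (!is.null(panel) && length(genes)) genes <- intersect_with_panel(genes, panel)
  if (!length(genes))
    stop_icistrat("signature is empty after loading/panel selection")
  structure(list(
    name = name,
    genes = genes,
    derivation = list(alpha = alpha, loading_threshold = loading_threshold,
                      n_significant = length(sig_genes),
                      n_loading_selected = n_before_panel,
                      n_final = length(genes),
                      intersected_panel = !is.null(panel),
                      explained = pca$explained,
                      de_model = "per-gene OLS on log2 normalized counts, t-based Wald p"),
    scores = ges_score(cm, genes)
  ), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes (%d significant -> %d by PC1 loading > %g%s)\n",
              x$name, length(x$genes), x$derivation$n_significant,
              x$derivation$n_loading_selected, x$derivation$loading_threshold,
              if (x$derivation$intersected_panel) " -> panel overlap" else ""))
  invisible(x)
}
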