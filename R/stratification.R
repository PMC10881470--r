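#' Relevance threshold for phenotype flags
#'
#' A treatment-induced fold change strictly greater than 1.2 versus control is
#' considered a relevant change for a response parameter.
#'
#' @param relevance_fc strict lower bound on a relevant linear fold change;
#'   must be > 1.
#' @return list of class `threshold_config`.
#' @export
threshold_config <- function(relevance_fc = 1.2) {
  if (!is.numeric(relevance_fc) || relevance_fc <= 1)
    stop_icistrat("relevance_fc must be > 1")
  structure(list(relevance_fc = relevance_fc), class = "threshold_config")
}

# Deterministic, permutation-invariant 2-means. Every optimal 2-means
# partition is linearly separable (the clusters lie on either side of the
# perpendicular bisector of their centers), so for 2-D embeddings of cohort
# size the global optimum is found by enumerating candidate projection
# directions (all point-pair differences) and every split along each sorted
# projection, scored by within-cluster sum of squares via prefix sums, then
# polished by Lloyd iterations. Clusters are constrained to hold at least
# min_size points: a sub-cohort must be large enough for the downstream
# rank tests (n >= 3 per group), and an unconstrained optimum happily
# isolates a single embedding outlier.
two_means <- function(Y, max_iter = 100L, min_size = 3L) {
  n <- nrow(Y)
  if (n < 2L || max(dist(Y)) == 0)
    stop_icistrat("degenerate embedding: all points identical")
  best_members <- NULL
  best_ss <- Inf
  dirs <- matrix(0, 0, ncol(Y))
  for (i in seq_len(n - 1L)) {
    d <- t(Y[(i + 1L):n, , drop = FALSE]) - Y[i, ]
    dirs <- rbind(dirs, t(d))
  }
  nrm <- sqrt(rowSums(dirs^2))
  dirs <- dirs[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  for (k in seq_len(nrow(dirs))) {
    ord <- order(as.vector(Y %*% dirs[k, ]))
    Ys <- Y[ord, , drop = FALSE]
    cs <- apply(Ys, 2L, cumsum)
    cs2 <- apply(Ys^2, 2L, cumsum)
    m <- seq_len(n - 1L)
    ss1 <- rowSums(cs2[m, , drop = FALSE] - cs[m, , drop = FALSE]^2 / m)
    ss2 <- rowSums(sweep(-cs2[m, , drop = FALSE], 2L, cs2[n, ], `+`) -
                     sweep(-cs[m, , drop = FALSE], 2L, cs[n, ], `+`)^2 / (n - m))
    tot <- ss1 + ss2
    lo <- min(min_size, floor(n / 2))
    tot[m < lo | (n - m) < lo] <- Inf
    mb <- which.min(tot)
    if (tot[mb] < best_ss - 1e-12) {
      best_ss <- tot[mb]
      best_members <- ord[seq_len(mb)]
    }
  }
  cl <- rep(2L, n); cl[best_members] <- 1L
  centers <- rbind(colMeans(Y[cl == 1L, , drop = FALSE]),
                   colMeans(Y[cl == 2L, , drop = FALSE]))
  for (it in seq_len(max_iter)) {   # Lloyd polish
    d1 <- colSums((t(Y) - centers[1L, ])^2)
    d2 <- colSums((t(Y) - centers[2L, ])^2)
    new_cl <- ifelse(d1 <= d2, 1L, 2L)
    if (min(table(factor(new_cl, 1:2))) < min(min_size, floor(n / 2)) ||
        identical(new_cl, cl)) break
    cl <- new_cl
    centers <- rbind(colMeans(Y[cl == 1L, , drop = FALSE]),
                     colMeans(Y[cl == 2L, , drop = FALSE]))
  }
  list(cluster = cl, centers = centers)
}

#' Primary SC1/SC2 split on the embedding
#'
#' Formalizes the visual cluster split as 2-means on the t-SNE coordinates.
#' The cluster with the higher mean IFNg log2 fold change is labeled SC1
#' (responders show significantly higher IFNg release); ties break by the
#' higher mean Perforin fold change.
#'
#' @param embedding n x 2 coordinates from [embed_tsne()].
#' @param fc_matrix the log2 fold-change matrix the embedding was computed
#'   from (needs `IFNg` and `Perforin` columns, same row order).
#' @return character vector (`"SC1"`/`"SC2"`), named by sample.
#' @export
split_primary <- function(embedding, fc_matrix) {
  Y <- as.matrix(embedding)
  fcm <- as.matrix(fc_matrix)
  stopifnot(nrow(Y) == nrow(fcm), all(c("IFNg", "Perforin") %in% colnames(fcm)))
  km <- two_means(Y)
  cl <- km$cluster
  sep <- sqrt(sum((km$centers[1L, ] - km$centers[2L, ])^2))
  spread <- mean(sqrt(rowSums((Y - km$centers[cl, , drop = FALSE])^2)))
  if (length(unique(cl)) < 2L || sep < 2 * spread)
    warn_icistrat("low separation between embedding clusters (center distance %.3g vs mean within-cluster spread %.3g)",
                  sep, spread)
  mean_ifng <- tapply(fcm[, "IFNg"], cl, mean)
  sc1 <- if (length(mean_ifng) < 2L || diff(range(mean_ifng)) == 0) {
    mean_perf <- tapply(fcm[, "Perforin"], cl, mean)
    as.integer(names(which.max(mean_perf)))
  } else as.integer(names(which.max(mean_ifng)))
  out <- ifelse(cl == sc1, "SC1", "SC2")
  names(out) <- rownames(fcm)
  out
}

#' Reinvigoration and cytotoxicity phenotype flags
#'
#' T-cell reinvigoration is read out as IFNg release fold change; tumor
#' cytotoxicity as tumor-content decrease (cytotoxicity-oriented fold change),
#' cleaved caspase-3 increase, or Perforin or GranzymeB release increase.
#' A flag is raised when the corresponding linear fold change is strictly
#' greater than the relevance threshold (default 1.2); the cytotoxicity
#' criteria combine by OR.
#'
#' @param fc named numeric vector of *linear* fold changes (a row of the
#'   `"linear"` attribute of [build_fc_matrix()]); needs `IFNg` and at least
#'   one of `tumor_content_cytotox`, `cleaved_caspase3`, `Perforin`,
#'   `GranzymeB`.
#' @param thr a [threshold_config()].
#' @return list with `reinvigoration`, `cytotoxicity` (logicals) and
#'   `evidence` (the fold changes consulted).
#' @export
phenotype_flags <- function(fc, thr = threshold_config()) {
  stopifnot(inherits(thr, "threshold_config"))
  fc <- unlist(fc)
  if (!"IFNg" %in% names(fc) || is.na(fc[["IFNg"]]))
    stop_icistrat("IFNg fold change required for the reinvigoration flag")
  cyto_params <- c("tumor_content_cytotox", "cleaved_caspase3", "Perforin", "GranzymeB")
  cyto_fc <- fc[intersect(cyto_params, names(fc))]
  cyto_fc <- cyto_fc[!is.na(cyto_fc)]
  if (!length(cyto_fc))
    stop_icistrat("all four cytotoxicity fold changes missing")
  t <- thr$relevance_fc
  list(reinvigoration = unname(fc[["IFNg"]] > t),
       cytotoxicity = unname(any(cyto_fc > t)),
       evidence = c(IFNg = unname(fc[["IFNg"]]), cyto_fc))
}

#' Assign the final sub-cohort label
#'
#' Primary SC1 samples stay SC1. Within SC2, the reinvigoration and
#' cytotoxicity flags define: SC2a (both), SC2b (cytotoxicity only),
#' SC2c (reinvigoration only), SC2d (neither; the non-responders).
#'
#' @param primary `"SC1"` or `"SC2"` (vectorized).
#' @param reinvigoration,cytotoxicity logical flags (vectorized).
#' @return character vector of labels in
#'   `{"SC1","SC2a","SC2b","SC2c","SC2d"}`.
#' @export
assign_subcohort <- function(primary, reinvigoration, cytotoxicity) {
  stopifnot(all(primary %in% c("SC1", "SC2")),
            is.logical(reinvigoration), is.logical(cytotoxicity))
  n <- length(primary)
  reinvigoration <- rep_len(reinvigoration, n)
  cytotoxicity <- rep_len(cytotoxicity, n)
  ifelse(primary == "SC1", "SC1",
    ifelse(reinvigoration & cytotoxicity, "SC2a",
      ifelse(!reinvigoration & cytotoxicity, "SC2b",
        ifelse(reinvigoration & !cytotoxicity, "SC2c", "SC2d"))))
}

#' Full sub-cohort stratification of a fold-change matrix
#'
#' Runs the complete stratification chain: t-SNE embedding of the log2
#' fold-change matrix, 2-means SC1/SC2 primary split, per-sample phenotype
#' flags from the linear fold changes, and the SC1/SC2a-d assignment.
#'
#' @param fcm an `fc_matrix` from [build_fc_matrix()] (or a log2 matrix with a
#'   `"linear"` attribute).
#' @param params a [tsne_params()].
#' @param thr a [threshold_config()].
#' @return data.frame with `sample_id`, `primary`, `sub`, `reinvigoration`,
#'   `cytotoxicity`, `qualified`; the embedding is attached as attribute
#'   `"embedding"`.
#' @export
stratify_cohort <- function(fcm, params = tsne_params(), thr = threshold_config()) {
  linear <- attr(fcm, "linear")
  if (is.null(linear)) linear <- 2^as.matrix(fcm)
  emb <- embed_tsne(fcm, params)
  primary <- split_primary(emb, fcm)
  flags <- lapply(seq_len(nrow(linear)), function(i) phenotype_flags(linear[i, ], thr))
  reinv <- vapply(flags, `[[`, logical(1), "reinvigoration")
  cyto <- vapply(flags, `[[`, logical(1), "cytotoxicity")
  out <- data.frame(sample_id = rownames(linear),
                    primary = unname(primary),
                    sub = assign_subcohort(primary, reinv, cyto),
                    reinvigoration = reinv,
                    cytotoxicity = cyto,
                    qualified = TRUE,
                    stringsAsFactors = FALSE)
  attr(out, "embedding") <- emb
  out
}
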