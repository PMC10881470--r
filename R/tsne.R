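# Exact (non Barnes-Hut) t-SNE. Cohort-scale inputs here are ~55 samples x 10
# parameters, where the O(n^2) gradient is trivial, so the original algorithm
# is implemented directly: per-point precision calibrated by bisection to the
# target perplexity, early exaggeration, momentum gradient descent.

#' t-SNE hyperparameters
#'
#' Defaults are the embedding settings used for the 10-parameter fold-change
#' matrix: perplexity 10, learning rate 100, 1000 iterations. The seed is part
#' of the result's provenance because the embedding is stochastic in its
#' initialization.
#'
#' @param perplexity effective neighborhood size; must be < n samples.
#' @param learning_rate gradient step size (eta).
#' @param n_iterations number of gradient iterations (>= 250).
#' @param seed integer seed for the random initialization.
#' @return list of class `tsne_params`.
#' @export
tsne_params <- function(perplexity = 10, learning_rate = 100,
                        n_iterations = 1000, seed = 42L) {
  stopifnot(perplexity > 0, learning_rate > 0)
  if (n_iterations < 250) stop_icistrat("n_iterations must be >= 250")
  structure(list(perplexity = perplexity, learning_rate = learning_rate,
                 n_iterations = n_iterations, seed = as.integer(seed)),
            class = "tsne_params")
}

# conditional probabilities p_{j|i} at the target perplexity via bisection
tsne_affinities <- function(d2, perplexity, tol = 1e-5, max_iter = 60L) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { h <- 0; p <- rep(0, length(di)) }
      else {
        p <- w / sw
        h <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) { beta_lo <- beta; beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2 }
      else { beta_hi <- beta; beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}

#' Embed a fold-change matrix in 2-D with t-SNE
#'
#' Exact t-SNE with early exaggeration (factor 12 for the first 250
#' iterations) and momentum (0.5, then 0.8 after iteration 250).
#' Initialization is the first two principal components rescaled to
#' standard deviation 1e-4 plus a tiny seeded jitter; PCA initialization
#' preserves the global arrangement of clusters (which pure random
#' initialization scrambles) and is the default of the reference t-SNE
#' implementations in this field. Rows are processed in sorted-rowname order
#' internally, so the embedding for each sample is invariant to the input
#' row order; results are returned in input order.
#'
#' @param fc_matrix numeric matrix, samples in rows (rownames = sample ids).
#' @param params a [tsne_params()].
#' @return n x 2 matrix of embedding coordinates (rownames preserved), with
#'   the params attached as attribute `"params"`.
#' @export
embed_tsne <- function(fc_matrix, params = tsne_params()) {
  X <- as.matrix(fc_matrix)
  n <- nrow(X)
  if (anyNA(X)) {
    bad <- rownames(X)[apply(is.na(X), 1L, any)] %||% which(apply(is.na(X), 1L, any))
    stop_icistrat("missing values in fold-change matrix for: %s",
                  paste(bad, collapse = ", "))
  }
  if (n <= params$perplexity)
    stop_icistrat("need more than perplexity (%g) samples, got %d",
                  params$perplexity, n)
  ord <- if (!is.null(rownames(X))) order(rownames(X)) else seq_len(n)
  X <- X[ord, , drop = FALSE]

  d2 <- as.matrix(dist(X))^2
  Pc <- tsne_affinities(d2, params$perplexity)
  P <- (Pc + t(Pc)) / (2 * n)
  P <- pmax(P, 1e-12)

  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  Y <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  if (ncol(Y) < 2L) Y <- cbind(Y, 0)
  if (sd(Y[, 1L]) > 0) Y <- Y / sd(Y[, 1L]) * 1e-4
  Y <- Y + with_seed(params$seed, matrix(rnorm(n * 2, sd = 1e-6), n, 2))
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  exag_until <- 250L
  for (iter in seq_len(params$n_iterations)) {
    exag <- if (iter <= exag_until) 12 else 1
    dy2 <- as.matrix(dist(Y))^2
    W <- 1 / (1 + dy2); diag(W) <- 0
    Q <- pmax(W / sum(W), 1e-12)
    M <- (P * exag - Q) * W
    grad <- 4 * (diag(rowSums(M)) - M) %*% Y
    momentum <- if (iter <= 250L) 0.5 else 0.8
    gains <- pmax(0.01, ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8))
    # step scaled down by the exaggeration factor during the early phase:
    # exaggerated attractive forces otherwise blow small embeddings apart
    inc <- momentum * inc - (params$learning_rate / exag) * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  out <- matrix(NA_real_, n, 2, dimnames = list(rownames(fc_matrix), c("tsne1", "tsne2")))
  out[ord, ] <- Y
  attr(out, "params") <- params
  out
}
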