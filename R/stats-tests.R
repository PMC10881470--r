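# Rank tests used throughout the pipeline. Exact null distributions are
# computed by convolution over the observed ranks (valid under ties, since the
# permutation distribution is conditional on the rank configuration); the
# normal approximation with tie correction takes over beyond the exact range.

# distribution of a subset-sum of (doubled, hence integer) ranks:
# returns counts over achievable sums for all 2^m subsets
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1L)  # index s+1 = count of subsets with sum s
  counts[1L] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  counts
}

# counts of rank-sums over all subsets of size n1 from ranks2 (doubled ranks)
rank_sum_counts <- function(ranks2, n1) {
  total <- sum(ranks2)
  # dp[[k]] = counts over sums using subsets of size k
  dp <- vector("list", n1 + 1L)
  dp[[1L]] <- c(1, numeric(total))
  for (k in seq_len(n1)) dp[[k + 1L]] <- numeric(total + 1L)
  for (r in ranks2) {
    for (k in rev(seq_len(n1))) {
      shifted <- c(rep(0, r), dp[[k]][seq_len(total + 1L - r)])
      dp[[k + 1L]] <- dp[[k + 1L]] + shifted
    }
  }
  dp[[n1 + 1L]]
}

two_sided_from_counts <- function(counts, stat2) {
  sums <- seq_along(counts) - 1L
  n_total <- sum(counts)
  lower <- sum(counts[sums <= stat2 + 1e-9]) / n_total
  upper <- sum(counts[sums >= stat2 - 1e-9]) / n_total
  min(1, 2 * min(lower, upper))
}

#' Compare two groups with the study's rank tests
#'
#' Wilcoxon matched-pairs signed-rank test for paired data and the
#' Mann-Whitney (Wilcoxon rank-sum) test for unpaired data, two-sided.
#' The exact conditional null distribution (computed by convolution over the
#' observed ranks, so ties are handled) is used for n <= 25 per group;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param values_a,values_b numeric vectors; equal length when `paired`.
#' @param paired logical; paired signed-rank vs unpaired rank-sum.
#' @return list with `statistic` (W+ rank sum of positive differences, or the
#'   Mann-Whitney U of `values_a`), `p`, `method`, and `n`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  if (paired) {
    if (length(values_a) != length(values_b))
      stop_icistrat("paired comparison needs equal lengths")
    if (length(values_a) < 3L) stop_icistrat("need n >= 3 per group")
    d <- values_a - values_b
    d <- d[d != 0]
    m <- length(d)
    if (m == 0L) {
      warn_icistrat("all paired differences are zero; p = 1")
      return(list(statistic = 0, p = 1, method = "signed_rank_degenerate", n = 0L))
    }
    r <- rank(abs(d))
    wpos <- sum(r[d > 0])
    if (m <= 25L) {
      counts <- signed_rank_counts(as.integer(round(2 * r)))
      p <- two_sided_from_counts(counts, 2 * wpos)
      method <- "signed_rank_exact"
    } else {
      mu <- m * (m + 1) / 4
      tie_tab <- table(r)
      sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
      z <- (wpos - mu - sign(wpos - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
      method <- "signed_rank_normal"
    }
    list(statistic = wpos, p = p, method = method, n = m)
  } else {
    n1 <- length(values_a); n2 <- length(values_b)
    if (n1 < 3L || n2 < 3L) stop_icistrat("need n >= 3 per group")
    r <- rank(c(values_a, values_b))
    w <- sum(r[seq_len(n1)])
    u <- w - n1 * (n1 + 1) / 2
    if (max(n1, n2) <= 25L) {
      counts <- rank_sum_counts(as.integer(round(2 * r)), n1)
      p <- two_sided_from_counts(counts, 2 * w)
      method <- "mann_whitney_exact"
    } else {
      n <- n1 + n2
      mu <- n1 * n2 / 2
      tie_tab <- table(r)
      sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
      if (sigma2 <= 0) return(list(statistic = u, p = 1,
                                   method = "mann_whitney_degenerate",
                                   n = c(n1, n2)))
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
      method <- "mann_whitney_normal"
    }
    list(statistic = u, p = p, method = method, n = c(n1, n2))
  }
}

# all permutations of 1..n as a matrix (n! rows); only used for small n
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Spearman correlation of response parameters against GES scores
#'
#' Nonparametric Spearman correlation with average-rank tie handling. The
#' two-sided p-value is exact (full permutation enumeration, conditional on
#' the observed tie patterns) for n <= 9 and the t approximation otherwise.
#'
#' @param param_table data.frame or matrix of parameters (one column each), or
#'   a single numeric vector.
#' @param ges_scores numeric vector, same length as the columns of
#'   `param_table`.
#' @return data.frame with `parameter`, `rho`, `p`, `n`. Constant parameters
#'   yield `NA` with a warning.
#' @export
spearman_correlate <- function(param_table, ges_scores) {
  if (is.numeric(param_table) && is.null(dim(param_table)))
    param_table <- data.frame(x = param_table)
  param_table <- as.data.frame(param_table)
  n <- length(ges_scores)
  stopifnot(nrow(param_table) == n)
  if (n < 4L) stop_icistrat("need n >= 4 pairs")
  res <- lapply(names(param_table), function(p) {
    x <- param_table[[p]]
    rho <- spearman_rho(x, ges_scores)
    if (is.na(rho)) {
      warn_icistrat("parameter %s is constant; Spearman rho undefined", p)
      return(data.frame(parameter = p, rho = NA_real_, p = NA_real_, n = n))
    }
    if (n <= 9L) {
      perms <- permutations_of(n)
      ry <- rank(ges_scores); rx <- rank(x)
      rhos <- apply(perms, 1L, function(idx) cor(rx, ry[idx]))
      pval <- mean(abs(rhos) >= abs(rho) - 1e-12)
    } else {
      tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
      pval <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    }
    data.frame(parameter = p, rho = rho, p = pval, n = n)
  })
  do.call(rbind, res)
}
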