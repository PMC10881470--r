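#' ROC curve, AUC and Youden cutoff for a GES classifier
#'
#' AUC by the rank (Mann-Whitney) formulation with average-rank tie handling.
#' Candidate thresholds are the midpoints between adjacent distinct scores;
#' at each, positivity is `score > threshold`. The Youden cutoff is the
#' smallest candidate maximizing `J = sensitivity + specificity - 1`.
#'
#' @param scores numeric scores (higher = more responder-like).
#' @param labels binary labels (0/1 or logical; 1 = responder).
#' @return list of class `roc_result`: `auc`, `operating_points` (data.frame
#'   threshold / sensitivity / specificity / J), `youden_cutoff`, `youden_J`.
#' @export
roc_youden <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_icistrat("both label classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  uniq <- sort(unique(scores))
  if (length(uniq) == 1L) {
    ops <- data.frame(threshold = uniq, sensitivity = 0, specificity = 1, J = 0)
  } else {
    thr <- (uniq[-length(uniq)] + uniq[-1L]) / 2
    sens <- vapply(thr, function(t) sum(scores > t & labels == 1L) / n1, 0)
    spec <- vapply(thr, function(t) sum(scores <= t & labels == 0L) / n0, 0)
    ops <- data.frame(threshold = thr, sensitivity = sens, specificity = spec,
                      J = sens + spec - 1)
  }
  best <- which(ops$J >= max(ops$J) - 1e-12)[1L]
  structure(list(auc = auc, operating_points = ops,
                 youden_cutoff = ops$threshold[best],
                 youden_J = ops$J[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f; Youden cutoff %.4g (J = %.3f)\n",
              x$auc, x$youden_cutoff, x$youden_J))
  invisible(x)
}

# Kaplan-Meier product-limit estimate for one group
km_curve <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  tt <- sort(unique(time[event == 1]))
  n <- length(time)
  surv <- numeric(length(tt)); at_risk <- integer(length(tt)); d <- integer(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    at_risk[i] <- sum(time >= tt[i])
    d[i] <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d[i] / at_risk[i])
    surv[i] <- s
  }
  data.frame(time = tt, n_risk = at_risk, n_event = d, surv = surv)
}

#' Kaplan-Meier split and log-rank (Mantel-Cox) test at a score cutoff
#'
#' Splits subjects into high (`score > cutoff`) and low groups, estimates the
#' Kaplan-Meier product-limit curve for each, and compares them with the
#' two-group log-rank test: observed-vs-expected events accumulated over the
#' pooled event times with the hypergeometric variance, chi-square with 1 df.
#'
#' @param records data.frame with `time` (> 0), `event` (1 = event,
#'   0 = censored) and `score`; or pass `cutoff = NULL` and a `group` column.
#' @param cutoff GES cutoff defining the high group (strictly greater).
#' @return list of class `km_logrank`: per-group KM curves (`km_high`,
#'   `km_low`), `observed`/`expected` events, `chisq`, `p`, group sizes.
#' @export
km_logrank <- function(records, cutoff) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  if (any(records$time <= 0)) stop_icistrat("times must be > 0")
  if (!all(records$event %in% c(0, 1))) stop_icistrat("event must be 0/1")
  if (!is.null(cutoff)) {
    stopifnot("score" %in% names(records))
    grp <- ifelse(records$score > cutoff, "high", "low")
  } else {
    stopifnot("group" %in% names(records))
    grp <- as.character(records$group)
  }
  if (length(unique(grp)) < 2L)
    stop_icistrat("both score groups must be non-empty after the cutoff split")
  groups <- sort(unique(grp))
  time <- records$time; event <- records$event
  if (any(tapply(event, grp, sum) == 0))
    warn_icistrat("a group has zero events; log-rank statistic still defined")
  tt <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  g1 <- grp == groups[1L]
  for (t in tt) {
    n_at <- sum(time >= t); n1_at <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1_at / n_at
    if (n_at > 1)
      v <- v + d * (n1_at / n_at) * (1 - n1_at / n_at) * (n_at - d) / (n_at - 1)
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- if (v > 0) pchisq(chisq, df = 1, lower.tail = FALSE) else 1
  structure(list(
    groups = groups,
    n = table(grp),
    km = setNames(lapply(groups, function(g) km_curve(time[grp == g], event[grp == g])),
                  groups),
    observed = c(o1, sum(event) - o1),
    expected = c(e1, sum(event) - e1),
    chisq = chisq, p = p
  ), class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> groups %s (n = %s); chi-square = %.4g, p = %.4g\n",
              paste(x$groups, collapse = "/"),
              paste(as.integer(x$n), collapse = "/"), x$chisq, x$p))
  invisible(x)
}
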