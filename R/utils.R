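# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# derive a child seed from a base seed and a stream index; kept < 2^31
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + 104729 * stream) %% 2147483647
}

geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# lognormal multiplicative noise with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_icistrat <- function(...) stop(sprintf(...), call. = FALSE)

warn_icistrat <- function(...) warning(sprintf(...), call. = FALSE)
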