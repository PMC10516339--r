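#' Run code with a temporary RNG seed
#'
#' Seeds the global RNG, evaluates `code`, and restores the caller's RNG
#' state afterwards, so seeded generators never perturb an enclosing
#' simulation stream. A `NULL` seed evaluates `code` with the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic sub-stream seed from a master seed
#'
#' All stochastic stages key their RNG off one master seed plus a string
#' label, so the full dataset is reproducible while stages stay independent.
#' The hash folds into `[0, 2^31 - 2]` (R integer range).
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the sub-stream.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(master, ...) {
  key <- paste(c(format(master), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 7
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

#' Stationary AR(1) series with unit marginal variance
#'
#' @param n_time number of timepoints.
#' @param k number of independent series (columns).
#' @param phi AR(1) coefficient, |phi| < 1.
#' @return `n_time` x `k` matrix; each column has mean 0, variance 1 in
#'   expectation, and lag-1 autocorrelation `phi`.
#' @keywords internal
ar1_matrix <- function(n_time, k, phi = 0.4) {
  stopifnot(n_time >= 1, k >= 1, abs(phi) < 1)
  x <- matrix(0, n_time, k)
  x[1L, ] <- stats::rnorm(k)
  if (n_time > 1L) {
    innov_sd <- sqrt(1 - phi^2)
    for (t in 2:n_time) {
      x[t, ] <- phi * x[t - 1L, ] + stats::rnorm(k, sd = innov_sd)
    }
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-score helper tolerant of constant input (returns zeros rather than NaN)
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
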