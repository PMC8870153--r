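# Internal helpers: seeded evaluation, seed derivation, truncated normals.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded package functions do
#' not disturb the caller's random number stream. A \code{NULL} seed evaluates
#' the expression with the current stream.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministic stream splitting: sub-seed i of a master seed, kept < 2^31.
deriveSeed <- function(seed, i) {
  ((as.double(seed) %% 2147483000) * 7919 + as.double(i) * 104729) %% 2147483629 + 1
}

# Normal truncated below at `lo` (default 0, open support requirement for
# latencies). sd = 0 degenerates to the constant mu.
rtnorm <- function(n, mu, sd, lo = 0, hi = Inf) {
  if (sd <= 0) return(rep(mu, n))
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, plo, phi), mu, sd)
}

isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x == round(x) && x > 0

stopf <- function(...) stop(sprintf(...), call. = FALSE)
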