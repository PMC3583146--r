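# Seeded simple random sampling without replacement, and the sampling
# context (n, N, pi) consumed by the estimators.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so seeded helpers do not perturb user
# simulations.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simple random sample without replacement
#'
#' Draws a record-level SRSWOR sample of size `round(fraction * N)` (at
#' least one record) from a population table.  The draw is deterministic
#' given the seed, and record order is preserved, so `fraction = 1` returns
#' the population unchanged.
#'
#' @param pop A [microdata] population.
#' @param fraction Sampling fraction pi in (0, 1\].
#' @param seed Integer seed; identical `(pop, fraction, seed)` give
#'   identical samples.
#' @return A [microdata] sample.
#' @export
srswor_sample <- function(pop, fraction, seed) {
  stopifnot(inherits(pop, "microdata"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  N <- nrow(pop)
  n <- max(1L, as.integer(round(fraction * N)))
  idx <- if (n == N) seq_len(N) else
    with_seed(seed, sort(sample.int(N, n)))
  microdata(as.data.frame(pop)[idx, , drop = FALSE], qi = qi_names(pop))
}

#' Sampling context
#'
#' Bundles the sample size n, population size N, and the derived sampling
#' fraction pi = n / N.  Estimators take the context rather than a free pi
#' to avoid inconsistent (n, N, pi) triples.
#'
#' @param n Sample size (>= 1).
#' @param N Population size (>= n).
#' @return An object of class `sampling_context` with fields `n`, `N`, `pi`.
#' @export
sampling_context <- function(n, N) {
  n <- as.integer(n); N <- as.integer(N)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (is.na(N) || N < n) stop("`N` must be >= n", call. = FALSE)
  structure(list(n = n, N = N, pi = n / N), class = "sampling_context")
}

#' @export
print.sampling_context <- function(x, ...) {
  cat(sprintf("Sampling context: n = %d, N = %d, pi = %.4g\n", x$n, x$N, x$pi))
  invisible(x)
}

# Validate that a spectrum is consistent with the declared sample size.
check_spectrum_context <- function(sp, ctx) {
  stopifnot(inherits(sp, "freq_spectrum"), inherits(ctx, "sampling_context"))
  if (sp$total != ctx$n) {
    stop(sprintf("spectrum totals %d records but context declares n = %d",
                 sp$total, ctx$n), call. = FALSE)
  }
  invisible(TRUE)
}
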