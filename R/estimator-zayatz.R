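# Zayatz estimator: model-free plug-in for P(F = 1 | f = 1).
#
# Under simple random sampling of n records from N, the number of a
# population class's j members that enter the sample is hypergeometric, so
#   P(f = 1 | F = j) = j C(N - j, n - 1) / C(N, n).
# The unknown population class-size distribution P(F = j) is replaced by
# the observed sample class-size distribution (spectrum proportions), and
# Bayes' rule gives
#   P_hat(F = 1 | f = 1) = P(f=1|F=1) s_1 / sum_j P(f=1|F=j) s_j,
# where s_j is the proportion of sample classes of size j.  The estimate
# scales the observed number of sample uniques:
#   lambda3_hat = u_1 * P_hat(F = 1 | f = 1) / (pi N).

#' Zayatz estimator of population uniqueness
#'
#' A closed-form, model-free estimator: the probability that a sample
#' unique is a population unique is estimated by plugging the observed
#' sample class-size distribution into exact hypergeometric subsampling
#' probabilities.  Always converges; at `pi = 1` it returns exactly
#' `u_1 / N`, the true population uniqueness.
#'
#' @inheritParams estimate_pitman
#' @return A `uniq_estimate` with `params$p_pop_unique_given_sample_unique`.
#' @export
estimate_zayatz <- function(sp, ctx) {
  check_spectrum_context(sp, ctx)
  n <- ctx$n; N <- ctx$N
  u1 <- spectrum_count(sp, 1L)
  if (u1 == 0L) {
    return(new_estimate("zayatz", 0, TRUE,
                        params = list(p_pop_unique_given_sample_unique = NA_real_),
                        diagnostics = list(note = "no sample uniques", clamped = FALSE)))
  }
  # P(f = 1 | F = j) for every observed class size j; dhyper computes
  # C(j,1) C(N-j, n-1) / C(N, n) stably in log space internally.
  p_f1_Fj <- stats::dhyper(1, m = sp$sizes, n = N - sp$sizes, k = n)
  w <- sp$counts / sp$num_classes
  denom <- sum(p_f1_Fj * w)
  p1 <- if (denom > 0) (p_f1_Fj[match(1L, sp$sizes)] * w[match(1L, sp$sizes)]) / denom
        else 0
  lam <- u1 * p1 / (ctx$pi * N)
  clamp_unit(new_estimate("zayatz", lam, TRUE,
                          params = list(p_pop_unique_given_sample_unique = p1),
                          diagnostics = list()))
}

# mu-argus (Benedetti-Franconi individual risk) estimator.
#
# The model takes the population size F of a sampled class to follow the
# negative-binomial posterior
#   P(F = k | f) = C(k-1, f-1) pi^f (1-pi)^(k-f),  k >= f,
# with the sampling fraction as the success parameter.  Extended to
# population uniqueness exactly as for Zayatz: sum the posterior singleton
# probability over the sample uniques and rescale,
#   lambda3_hat = u_1 * P(F = 1 | f = 1) / (pi N).

#' mu-argus estimator of population uniqueness
#'
#' Applies the Benedetti–Franconi individual-risk model, in which the
#' population class size given an observed sample class size follows a
#' negative-binomial posterior with the sampling fraction as parameter, and
#' extends it to a population-uniqueness estimate by summing the posterior
#' probability of population uniqueness over the sample uniques.  A
#' deterministic closed form; always converges.
#'
#' @inheritParams estimate_pitman
#' @return A `uniq_estimate` with `params$p_pop_unique_given_sample_unique`.
#' @export
estimate_mu_argus <- function(sp, ctx) {
  check_spectrum_context(sp, ctx)
  u1 <- spectrum_count(sp, 1L)
  if (u1 == 0L) {
    return(new_estimate("mu_argus", 0, TRUE,
                        params = list(p_pop_unique_given_sample_unique = NA_real_),
                        diagnostics = list(note = "no sample uniques", clamped = FALSE)))
  }
  # P(F = 1 | f = 1) = dnbinom(0, size = 1, prob = pi) = pi
  p1 <- stats::dnbinom(0, size = 1, prob = ctx$pi)
  lam <- u1 * p1 / (ctx$pi * ctx$N)
  clamp_unit(new_estimate("mu_argus", lam, TRUE,
                          params = list(p_pop_unique_given_sample_unique = p1),
                          diagnostics = list()))
}

#' Run all four uniqueness estimators
#'
#' Runs Pitman, SNB, Zayatz and mu-argus on the same spectrum, in that
#' fixed order.  Individual estimator failures are captured as
#' `converged = FALSE` results; this function never raises for them.
#'
#' @inheritParams estimate_pitman
#' @return A named list of four `uniq_estimate` objects
#'   (`pitman`, `snb`, `zayatz`, `mu_argus`).
#' @export
estimate_all <- function(sp, ctx) {
  fns <- list(pitman = estimate_pitman, snb = estimate_snb,
              zayatz = estimate_zayatz, mu_argus = estimate_mu_argus)
  out <- lapply(names(fns), function(nm) {
    tryCatch(fns[[nm]](sp, ctx), error = function(e) {
      new_estimate(nm, NA_real_, FALSE,
                   diagnostics = list(error = conditionMessage(e)))
    })
  })
  names(out) <- names(fns)
  out
}
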