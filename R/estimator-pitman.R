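# Pitman (two-parameter Poisson-Dirichlet) estimator of population
# uniqueness.  The sample partition is modelled by the Pitman sampling
# formula with discount 0 <= alpha < 1 and concentration theta > -alpha
# (alpha = 0 recovers the Ewens model).  (alpha, theta) are fitted by
# maximum likelihood on the sample's frequency spectrum and lambda3 is the
# predictive expected proportion of singleton classes in a partition of the
# population size N.

.PITMAN_ALPHA_EPS <- 1e-6

# Log-likelihood of a spectrum under the Pitman sampling formula:
#   sum_{i=1}^{u-1} log(theta + i alpha)
#   - sum_{i=1}^{n-1} log(theta + i)
#   + sum_{classes, f_j >= 2} sum_{i=1}^{f_j - 1} log(i - alpha)
pitman_loglik <- function(alpha, theta, sp) {
  n <- sp$total; u <- sp$num_classes
  if (alpha < 0 || alpha >= 1 || theta <= -alpha) return(-Inf)
  t1 <- if (u >= 2L) {
    if (alpha > 0) {
      (u - 1) * log(alpha) + lgamma(theta / alpha + u) - lgamma(theta / alpha + 1)
    } else {
      (u - 1) * log(theta)
    }
  } else 0
  t2 <- lgamma(theta + n) - lgamma(theta + 1)
  big <- sp$sizes >= 2L
  t3 <- if (any(big)) {
    sum(sp$counts[big] * (lgamma(sp$sizes[big] - alpha) - lgamma(1 - alpha)))
  } else 0
  t1 - t2 + t3
}

pitman_grad <- function(alpha, theta, sp) {
  n <- sp$total; u <- sp$num_classes
  i <- seq_len(max(u - 1L, 0L))
  d_alpha <- if (u >= 2L) sum(i / (theta + i * alpha)) else 0
  d_theta <- if (u >= 2L) sum(1 / (theta + i * alpha)) else 0
  d_theta <- d_theta - (digamma(theta + n) - digamma(theta + 1))
  big <- sp$sizes >= 2L
  if (any(big)) {
    # d/d alpha [lgamma(j - alpha) - lgamma(1 - alpha)] =
    #   digamma(1 - alpha) - digamma(j - alpha)
    d_alpha <- d_alpha +
      sum(sp$counts[big] * (digamma(1 - alpha) - digamma(sp$sizes[big] - alpha)))
  }
  c(alpha = d_alpha, theta = d_theta)
}

#' Predictive expected singleton proportion under the Pitman model
#'
#' The expected number of size-one equivalence classes in a population of
#' size `N` generated by the Pitman model with parameters `(alpha, theta)`,
#' divided by `N`:
#' \deqn{E[M_1(N)]/N = (\theta + \alpha)
#'   \frac{\Gamma(\theta + \alpha + N - 1)}{\Gamma(\theta + \alpha + 1)}
#'   \frac{\Gamma(\theta + 1)}{\Gamma(\theta + N)}.}
#' At `alpha = 0` this reduces to the Ewens form
#' `E[M_1(N)]/N = theta / (theta + N - 1)`.
#'
#' @param alpha Discount parameter in \[0, 1).
#' @param theta Concentration parameter, > -alpha.
#' @param N Population size.
#' @return The expected proportion of population singletons.
#' @export
pitman_expected_singletons <- function(alpha, theta, N) {
  if (theta + alpha <= 0) return(0)
  exp(log(theta + alpha) +
        lgamma(theta + alpha + N - 1) - lgamma(theta + alpha + 1) +
        lgamma(theta + 1) - lgamma(theta + N))
}

#' Pitman estimator of population uniqueness
#'
#' Fits the two-parameter Pitman sampling formula to the sample spectrum by
#' box-constrained quasi-Newton maximum likelihood with a 3 x 3 multi-start
#' grid (alpha in \{0.01, 0.5, 0.9\}, theta in \{1, 10, 100\}), then reports
#' the predictive expected proportion of population singletons at the
#' fitted parameters (see [pitman_expected_singletons()]).
#'
#' An all-singleton sample (u = n) drives the discount to its upper
#' boundary; the fit is then reported as converged with `alpha` clamped at
#' `1 - 1e-6` and a boundary flag in the diagnostics.
#'
#' @param sp A [spectrum_of()] frequency spectrum of the sample.
#' @param ctx A [sampling_context()] with the sample and population sizes.
#' @return A `uniq_estimate` with `params$alpha`, `params$theta`.
#' @export
estimate_pitman <- function(sp, ctx) {
  check_spectrum_context(sp, ctx)
  eps <- .PITMAN_ALPHA_EPS

  # Unconstrained theta via theta = exp(phi) - alpha keeps theta > -alpha
  # for any alpha in the box.
  negll <- function(par) {
    alpha <- par[1]; theta <- exp(par[2]) - alpha
    ll <- pitman_loglik(alpha, theta, sp)
    if (!is.finite(ll)) 1e12 else -ll
  }
  neggr <- function(par) {
    alpha <- par[1]; theta <- exp(par[2]) - alpha
    g <- pitman_grad(alpha, theta, sp)
    # d/d alpha at fixed phi: partial_alpha + partial_theta * (-1)
    c(-(g[1] - g[2]), -(g[2] * exp(par[2])))
  }

  starts <- expand.grid(alpha = c(0.01, 0.5, 0.9), theta = c(1, 10, 100))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    par0 <- c(starts$alpha[s], log(starts$theta[s] + starts$alpha[s]))
    fit <- tryCatch(
      stats::optim(par0, negll, neggr, method = "L-BFGS-B",
                   lower = c(0, -30), upper = c(1 - eps, 30),
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  if (is.null(best)) {
    return(new_estimate("pitman", NA_real_, FALSE,
                        diagnostics = list(error = "all optimizer starts failed")))
  }

  # the likelihood can be very flat in theta; polish with damped Newton
  # steps when the returned gradient is not yet small
  if (max(abs(neggr(best$par))) >= 1e-6) {
    pol <- newton_polish(best$par, negll, neggr,
                         lower = c(0, -30), upper = c(1 - eps, 30))
    if (pol$value <= best$value + 1e-9) {
      best$par <- pol$par; best$value <- pol$value
    }
  }

  alpha_hat <- best$par[1]
  theta_hat <- exp(best$par[2]) - alpha_hat
  boundary <- alpha_hat >= 1 - eps - 1e-9 || alpha_hat <= 1e-9 ||
    best$par[2] <= -30 + 1e-9
  # a vanishing gradient at an interior optimum is convergence even when a
  # start's line search ended abnormally
  grad_norm <- max(abs(neggr(best$par)))
  lam <- pitman_expected_singletons(alpha_hat, theta_hat, ctx$N)
  est <- new_estimate(
    "pitman", lam,
    converged = best$convergence == 0 || boundary || grad_norm < 1e-5,
    params = list(alpha = alpha_hat, theta = theta_hat),
    diagnostics = list(loglik = -best$value,
                       boundary = boundary,
                       gradient_norm = grad_norm,
                       optim_convergence = best$convergence,
                       iterations = unname(best$counts[1]))
  )
  clamp_unit(est)
}
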