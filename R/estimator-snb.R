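# Slide (shifted) negative binomial superpopulation estimator.
#
# Population equivalence-class sizes are modelled as F = 1 + G with
# G ~ NegBin(size = r, prob = p), so P(F = j) = C(j-2+r, j-1) p^r (1-p)^(j-1)
# for j >= 1 and the population singleton probability is P(F = 1) = p^r.
#
# Under binomial subsampling with rate pi each class member enters the
# sample independently, so the sample class size decomposes as
# f = Bernoulli(pi) + Thin_pi(G), and the thinned negative binomial is
# again negative binomial with size r and prob q = p / (p + pi (1 - p)).
# The marginal sample-size law is therefore
#   P(f = k) = (1 - pi) h(k) + pi h(k - 1),   h = NegBin(r, q) pmf,
# and observed classes are those with f >= 1.  (r, p) are fitted by maximum
# likelihood on the observed spectrum (zero-truncated multinomial); the
# number of population classes K is implied by the fit rather than assumed
# known: K_hat = u / P(f >= 1) and lambda3_hat = K_hat p^r / N.

snb_q <- function(p, pi) p / (p + pi * (1 - p))

# Marginal sample class-size probabilities P(f = k) for k in `ks` (k >= 0).
snb_pf <- function(ks, r, p, pi) {
  q <- snb_q(p, pi)
  h  <- stats::dnbinom(ks, size = r, prob = q)
  h1 <- ifelse(ks >= 1L, stats::dnbinom(ks - 1L, size = r, prob = q), 0)
  (1 - pi) * h + pi * h1
}

# Negative log-likelihood of the observed (zero-truncated) spectrum, on the
# unconstrained scale par = (log r, logit p).
snb_negll <- function(par, sp, pi) {
  r <- exp(par[1]); p <- stats::plogis(par[2])
  if (!is.finite(r) || r <= 0 || p <= 0 || p >= 1) return(1e12)
  pk <- snb_pf(sp$sizes, r, p, pi)
  p0 <- snb_pf(0L, r, p, pi)
  if (any(pk <= 0) || p0 >= 1) return(1e12)
  ll <- sum(sp$counts * log(pk)) - sp$num_classes * log1p(-p0)
  if (!is.finite(ll)) 1e12 else -ll
}

snb_negll_grad <- function(par, sp, pi) {
  r <- exp(par[1]); p <- stats::plogis(par[2])
  q <- snb_q(p, pi)
  dq_dp <- pi / (p + pi * (1 - p))^2

  # d log h(k) / d r and d log h(k) / d q for NegBin(r, q)
  hk <- function(k) stats::dnbinom(k, size = r, prob = q)
  dh <- function(k) {
    h <- hk(k)
    dr <- h * (digamma(k + r) - digamma(r) + log(q))
    dqv <- h * (r / q - k / (1 - q))
    list(h = h, dr = dr, dq = dqv)
  }
  dPk <- function(ks) {
    a <- dh(ks)
    b <- dh(pmax(ks - 1L, 0L))
    has1 <- ks >= 1L
    list(P  = (1 - pi) * a$h + pi * ifelse(has1, b$h, 0),
         dr = (1 - pi) * a$dr + pi * ifelse(has1, b$dr, 0),
         dq = (1 - pi) * a$dq + pi * ifelse(has1, b$dq, 0))
  }
  obs <- dPk(sp$sizes)
  z <- dh(0L)
  P0 <- (1 - pi) * z$h; dP0r <- (1 - pi) * z$dr; dP0q <- (1 - pi) * z$dq

  # d/d theta [-u log(1 - P0)] contributes +u dP0 / (1 - P0)
  dll_dr <- sum(sp$counts * obs$dr / obs$P) + sp$num_classes * dP0r / (1 - P0)
  dll_dq <- sum(sp$counts * obs$dq / obs$P) + sp$num_classes * dP0q / (1 - P0)
  dll_dp <- dll_dq * dq_dp
  # chain rule to the unconstrained scale
  g <- c(dll_dr * r, dll_dp * p * (1 - p))
  if (any(!is.finite(g))) g <- c(0, 0)
  -g
}

.SNB_GRAD_TOL <- 1e-6
.SNB_MAXIT <- 500L

#' Slide negative binomial estimator of population uniqueness
#'
#' Fits a shifted negative binomial superpopulation law for the population
#' equivalence-class sizes to the sample spectrum by maximum likelihood
#' under binomial subsampling, with the number of population classes
#' estimated as part of the fit rather than assumed known.  The estimate is
#' `lambda3_hat = K_hat * P(F = 1) / N` with `K_hat = u / P(f >= 1)`.
#'
#' Convergence is declared only when the optimizer terminates within its
#' iteration budget (500) with gradient sup-norm below `1e-6` on the
#' unconstrained scale; otherwise `converged = FALSE` and `lambda3_hat` is
#' `NA` — there is no silent fallback, because the E1 decision rule branches
#' on this flag.
#'
#' @inheritParams estimate_pitman
#' @return A `uniq_estimate` with `params$r` (dispersion), `params$p`
#'   (success probability; `P(F = 1) = p^r`) and `params$K_hat`.
#' @export
estimate_snb <- function(sp, ctx) {
  check_spectrum_context(sp, ctx)
  pi <- ctx$pi

  starts <- expand.grid(r = c(0.2, 1, 5), p = c(0.1, 0.5, 0.9))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    par0 <- c(log(starts$r[s]), stats::qlogis(starts$p[s]))
    fit <- tryCatch(
      stats::optim(par0, snb_negll, snb_negll_grad, sp = sp, pi = pi,
                   method = "L-BFGS-B", lower = c(-12, -12), upper = c(12, 12),
                   control = list(maxit = .SNB_MAXIT, factr = 1e3, pgtol = 1e-9)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e12) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  # the (r, p) likelihood ridge can be flat enough that L-BFGS-B halts on
  # function-value change short of the gradient tolerance; polish with a
  # few damped Newton steps on the analytic gradient
  if (!is.null(best) && max(abs(snb_negll_grad(best$par, sp, pi))) >= .SNB_GRAD_TOL) {
    pol <- newton_polish(best$par,
                         function(p) snb_negll(p, sp, pi),
                         function(p) snb_negll_grad(p, sp, pi),
                         lower = c(-12, -12), upper = c(12, 12))
    if (pol$value <= best$value + 1e-9) {
      best$par <- pol$par; best$value <- pol$value; best$convergence <- 0L
    }
  }

  if (is.null(best)) {
    return(new_estimate("snb", NA_real_, FALSE,
                        diagnostics = list(error = "likelihood fit failed at every start")))
  }

  grad_norm <- max(abs(snb_negll_grad(best$par, sp, pi)))
  on_box <- any(abs(best$par) >= 12 - 1e-8)
  converged <- best$convergence == 0 && grad_norm < .SNB_GRAD_TOL && !on_box

  r_hat <- exp(best$par[1]); p_hat <- stats::plogis(best$par[2])
  p_obs <- 1 - snb_pf(0L, r_hat, p_hat, pi)
  K_hat <- sp$num_classes / p_obs
  lam <- K_hat * p_hat^r_hat / ctx$N

  diagnostics <- list(loglik = -best$value, gradient_norm = grad_norm,
                      boundary = on_box, optim_convergence = best$convergence,
                      iterations = unname(best$counts[1]))
  if (!converged) {
    return(new_estimate("snb", NA_real_, FALSE,
                        params = list(r = r_hat, p = p_hat, K_hat = K_hat),
                        diagnostics = diagnostics))
  }
  clamp_unit(new_estimate("snb", lam, TRUE,
                          params = list(r = r_hat, p = p_hat, K_hat = K_hat),
                          diagnostics = diagnostics))
}
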