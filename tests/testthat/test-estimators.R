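# The four population-uniqueness estimators against their independent
# oracles: Chinese-restaurant-process simulation for Pitman, exact
# arithmetic for Zayatz, an independent posterior evaluation for mu-argus,
# and self-consistency for the slide negative binomial.

test_that("Pitman predictive singleton formula matches the CRP oracle", {
  # Ewens submodel (alpha = 0): candidate closed form theta*N/(theta+N-1)
  theta <- 20; N <- 2000L; reps <- 10000L
  m1 <- with_test_seed(41, uniqrisk:::crp_singleton_counts_cpp(reps, N, 0, theta))
  closed <- theta * N / (theta + N - 1)
  se <- stats::sd(m1) / sqrt(reps)
  expect_lt(abs(mean(m1) - closed), 3 * se)
  expect_equal(N * pitman_expected_singletons(0, theta, N), closed)

  # general case (alpha > 0): the rising-factorial predictive form
  alpha <- 0.25; N2 <- 1000L
  m1b <- with_test_seed(42, uniqrisk:::crp_singleton_counts_cpp(reps, N2, alpha, theta))
  pred <- N2 * pitman_expected_singletons(alpha, theta, N2)
  se2 <- stats::sd(m1b) / sqrt(reps)
  expect_lt(abs(mean(m1b) - pred), 3 * se2)
})

test_that("Pitman MLE recovers CRP parameters across 200 replicates", {
  res <- t(sapply(1:200, function(s) {
    pop <- generate_crp_population(2000, 0.25, 20, seed = s)
    est <- estimate_pitman(spectrum_of(pop), sampling_context(2000, 2000))
    if (!est$converged) return(c(a = NA_real_, th = NA_real_))
    c(a = est$params$alpha, th = est$params$theta)
  }))
  expect_gte(mean(!is.na(res[, "a"])), 0.95)
  # discount recovered within +-0.1 in at least 90% of replicates
  # (non-converged replicates count as recovery failures)
  expect_gte(mean(!is.na(res[, "a"]) & abs(res[, "a"] - 0.25) <= 0.1), 0.90)
  # concentration: median lands within +-50% of the truth, and the
  # per-replicate +-50% rate is high (its sampling spread is wider)
  med_th <- stats::median(res[, "th"], na.rm = TRUE)
  expect_true(med_th >= 10 && med_th <= 30)
  expect_gte(mean(!is.na(res[, "th"]) & res[, "th"] >= 10 & res[, "th"] <= 30), 0.80)
})

test_that("Pitman MLE is a local optimum and handles degenerate spectra", {
  pop <- generate_crp_population(500, 0.3, 10, seed = 11)
  sp <- spectrum_of(pop); ctx <- sampling_context(500, 500)
  est <- estimate_pitman(sp, ctx)
  ll_hat <- est$diagnostics$loglik
  a <- est$params$alpha; th <- est$params$theta
  for (da in c(-0.01, 0, 0.01)) for (dt in c(-0.01, 0, 0.01)) {
    a2 <- a + da; t2 <- th + dt
    if (a2 >= 0 && a2 < 1 && t2 > -a2) {
      expect_lte(uniqrisk:::pitman_loglik(a2, t2, sp), ll_hat + 1e-7)
    }
  }

  # one class containing everyone: essentially no evidence of uniqueness
  sp1 <- spectrum_from_map(list(`200` = 1L))
  est1 <- estimate_pitman(sp1, sampling_context(200, 400))
  expect_lte(est1$lambda3_hat, 1 / 400)

  # all singletons: discount driven to the upper boundary, flagged
  spu <- spectrum_from_map(list(`1` = 150L))
  estu <- estimate_pitman(spu, sampling_context(150, 300))
  expect_true(estu$converged)
  expect_true(estu$diagnostics$boundary)
  expect_gte(estu$params$alpha, 1 - 1e-5)
  expect_true(estu$lambda3_hat >= 0 && estu$lambda3_hat <= 1)
})

test_that("SNB estimator is self-consistent on data from its own model", {
  # population classes F = 1 + NegBin(r = 1, p = 0.4); pi = 0.5
  rb <- rep(NA_real_, 200)
  conv <- logical(200)
  for (s in 1:200) {
    pop <- snb_population(K = 800, r = 1, p = 0.4, seed = 5000 + s)
    truth <- lambda3(pop)
    md <- as_microdata(pop)
    smp <- srswor_sample(md, 0.5, seed = 6000 + s)
    sp <- spectrum_of(build_equivalence_classes(smp))
    est <- estimate_snb(sp, sampling_context(nrow(smp), pop$total))
    conv[s] <- est$converged
    if (est$converged) rb[s] <- relative_bias(est$lambda3_hat, truth)
  }
  expect_gte(mean(conv), 0.5)
  expect_lt(abs(stats::median(rb, na.rm = TRUE)), 0.15)
})

test_that("SNB surfaces failure as a flag, never a silent number", {
  # all-singleton spectrum at a tiny sampling fraction: a documented
  # stress case; whether or not the fit converges, the contract holds
  sp <- spectrum_from_map(list(`1` = 60L))
  est <- estimate_snb(sp, sampling_context(60, 6000))
  if (!est$converged) {
    expect_true(is.na(est$lambda3_hat))
  } else {
    expect_true(est$lambda3_hat >= 0 && est$lambda3_hat <= 1)
  }
  expect_type(est$converged, "logical")
})

test_that("SNB at full sampling recovers the exact uniqueness", {
  pop <- snb_population(K = 900, r = 1.5, p = 0.45, seed = 77)
  sp <- spectrum_of(pop)
  est <- estimate_snb(sp, sampling_context(pop$total, pop$total))
  expect_true(est$converged)
  expect_lt(abs(est$lambda3_hat - lambda3(pop)), 0.02)
})

test_that("Zayatz estimator matches an exact-arithmetic oracle", {
  # spectrum {1:3, 2:2, 3:1}, n = 10, N = 20: evaluate every
  # hypergeometric term with exact integer choose() arithmetic
  sp <- spectrum_from_map(list(`1` = 3L, `2` = 2L, `3` = 1L))
  ctx <- sampling_context(10, 20)
  est <- estimate_zayatz(sp, ctx)

  p_f1 <- function(j, n, N) j * choose(N - j, n - 1) / choose(N, n)
  u <- 6
  num <- p_f1(1, 10, 20) * (3 / u)
  den <- num + p_f1(2, 10, 20) * (2 / u) + p_f1(3, 10, 20) * (1 / u)
  oracle <- 3 * (num / den) / (0.5 * 20)
  expect_equal(est$lambda3_hat, oracle, tolerance = 1e-12)
  expect_true(est$converged)
})

test_that("Zayatz is exact at full sampling and zero without sample uniques", {
  pop <- generate_crp_population(400, 0.2, 6, seed = 9)
  sp <- spectrum_of(pop)
  est <- estimate_zayatz(sp, sampling_context(pop$total, pop$total))
  expect_equal(est$lambda3_hat, lambda3(pop), tolerance = 1e-12)

  sp0 <- spectrum_from_map(list(`2` = 5L, `3` = 2L))
  est0 <- estimate_zayatz(sp0, sampling_context(16, 64))
  expect_equal(est0$lambda3_hat, 0)
})

test_that("mu-argus matches an independent posterior evaluation", {
  # fixed spectrum {1:5, 2:3}, n = 11, pi = 0.1: re-derive
  # P(F = 1 | f = 1) by brute-force evaluation of the normalized
  # negative-binomial posterior sum
  sp <- spectrum_from_map(list(`1` = 5L, `2` = 3L))
  ctx <- sampling_context(11, 110)
  est <- estimate_mu_argus(sp, ctx)

  pi <- 11 / 110
  ks <- 1:5000
  post <- choose(ks - 1, 0) * pi^1 * (1 - pi)^(ks - 1)
  expect_equal(sum(post), 1, tolerance = 1e-10)     # posterior normalizes
  p1 <- post[1]
  oracle <- 5 * p1 / (pi * 110)
  expect_equal(est$lambda3_hat, oracle, tolerance = 1e-12)

  # full sampling: posterior degenerates to the sample itself
  pop <- generate_crp_population(300, 0.1, 4, seed = 13)
  spf <- spectrum_of(pop)
  estf <- estimate_mu_argus(spf, sampling_context(pop$total, pop$total))
  expect_equal(estf$lambda3_hat, lambda3(pop), tolerance = 1e-12)

  # no sample uniques -> zero
  sp0 <- spectrum_from_map(list(`4` = 3L))
  expect_equal(estimate_mu_argus(sp0, sampling_context(12, 40))$lambda3_hat, 0)
})

test_that("estimators are deterministic functions of the spectrum alone", {
  pop <- as_microdata(generate_crp_population(600, 0.25, 12, seed = 21))
  smp <- srswor_sample(pop, 0.4, seed = 22)
  perm <- with_test_seed(23, {
    idx <- sample(nrow(smp))
    microdata(as.data.frame(smp)[idx, , drop = FALSE], qi = qi_names(smp))
  })
  ctx <- sampling_context(nrow(smp), 600)
  sp1 <- spectrum_of(build_equivalence_classes(smp))
  sp2 <- spectrum_of(build_equivalence_classes(perm))
  e1s <- estimate_all(sp1, ctx)
  e2s <- estimate_all(sp2, ctx)
  for (nm in names(e1s)) {
    expect_identical(e1s[[nm]]$lambda3_hat, e2s[[nm]]$lambda3_hat, info = nm)
  }
  # closed forms are bit-identical on repeated calls
  expect_identical(estimate_zayatz(sp1, ctx)$lambda3_hat,
                   estimate_zayatz(sp1, ctx)$lambda3_hat)
  expect_identical(estimate_mu_argus(sp1, ctx)$lambda3_hat,
                   estimate_mu_argus(sp1, ctx)$lambda3_hat)
})

test_that("estimate_all always returns four results in stable order", {
  sp <- spectrum_from_map(list(`1` = 4L, `2` = 2L))
  ctx <- sampling_context(8, 80)
  res <- estimate_all(sp, ctx)
  expect_named(res, c("pitman", "snb", "zayatz", "mu_argus"))
  for (nm in names(res)) {
    r <- res[[nm]]
    if (r$converged) expect_true(r$lambda3_hat >= 0 && r$lambda3_hat <= 1)
    else expect_true(is.na(r$lambda3_hat))
  }
})
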