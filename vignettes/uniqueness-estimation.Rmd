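---
title: "Estimating population uniqueness from a disclosed sample"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating population uniqueness from a disclosed sample}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniqrisk)
```

## The problem

When a clinical data set is disclosed for secondary use, an adversary may
try to re-identify patients by matching the disclosed records against a
public or semi-public registry (a voter list, court records, professional
directories) on *quasi-identifiers*: variables such as age, sex, postal
code, and admission or birth dates that the adversary can plausibly know.
Records sharing identical values on all quasi-identifiers form an
*equivalence class*; a record alone in its class is *unique*. A match is
certain only when a record is unique in **both** the disclosed data set
and the registry, so uniqueness — not the mere count of rare-looking
records — is the operative measure of risk.

Three exact metrics apply when the registry (the "population", size $N$)
is available next to the disclosed sample (size $n$). Writing $f_i$ and
$F_i$ for sample and population class sizes and $I$ for the indicator
function:

* $\lambda_1 = \sum_i I(f_i{=}1, F_i{=}1) \big/ \sum_i I(f_i{=}1)$ — the
  probability a record is population-unique given it is sample-unique.
  Undefined when the sample has no uniques (an empty conditioning set);
  `lambda1()` returns `NA` there rather than 0.
* $\lambda_2 = \sum_i I(f_i{=}1, F_i{=}1) / n$ — the share of the
  disclosed data set actually at risk. Always defined; 0 without sample
  uniques. Note $\lambda_2 = \lambda_1 \cdot u_1/n$ ($u_1$ = number of
  sample uniques), so $\lambda_2 \le \lambda_1$.
* $\lambda_3 = \sum_i I(F_i{=}1) / N$ — the proportion of the population
  that is unique. Under equal-probability sampling, $E[\lambda_2] =
  \lambda_3$ exactly, which is why $\lambda_3$ is the quantity the
  sample-only estimators target.

```{r}
ex <- worked_example()
ex$small
```

A custodian who assumed every sample unique would match would act on the
64% figure and over-protect; the data-set risk is the 0.14.

## Estimating $\lambda_3$ from the sample alone

In practice the registry is usually not acquirable, and $\lambda_3$ must
be estimated from the sample's *frequency spectrum* — the number of
classes of each size, a sufficient statistic for everything here — plus
$(n, N)$. Four estimators are implemented; all consume only
`(spectrum_of(...), sampling_context(n, N))`, so permuting records or
relabelling classes cannot change an estimate.

**Pitman** (`estimate_pitman`). The sample partition is modelled by the
two-parameter Pitman sampling formula with discount $0 \le \alpha < 1$
and concentration $\theta > -\alpha$ (the Ewens model is $\alpha = 0$).
The log-likelihood of a spectrum with $u$ classes is

$$\log L(\alpha,\theta) = \sum_{i=1}^{u-1}\log(\theta+i\alpha)
  - \sum_{i=1}^{n-1}\log(\theta+i)
  + \sum_{f_j \ge 2}\sum_{i=1}^{f_j-1}\log(i-\alpha),$$

maximized under box constraints with a $3\times3$ multi-start grid
($\alpha \in \{0.01, 0.5, 0.9\}$, $\theta \in \{1, 10, 100\}$), because
the likelihood can be nearly flat in $\theta$. The estimate is the
predictive expected proportion of singleton classes in a population-sized
partition at the fitted parameters,

$$\hat\lambda_3 = E[M_1(N)]/N = (\theta+\alpha)
  \frac{\Gamma(\theta+\alpha+N-1)}{\Gamma(\theta+\alpha+1)}
  \frac{\Gamma(\theta+1)}{\Gamma(\theta+N)},$$

which reduces to $\theta/(\theta+N-1)$ at $\alpha = 0$. The form was
validated against a Chinese-restaurant-process Monte Carlo oracle (both
the Ewens case and the general case) before being frozen into the tests.

**Slide negative binomial** (`estimate_snb`). Population class sizes are
modelled as $F = 1 + G$, $G \sim \mathrm{NegBin}(r, p)$, so
$P(F{=}1) = p^r$. Under binomial subsampling at rate $\pi = n/N$ the
sample class size is $f = \mathrm{Bernoulli}(\pi) + G'$ with
$G' \sim \mathrm{NegBin}(r, q)$, $q = p/(p + \pi(1-p))$ (thinning a
negative binomial preserves the family). $(r, p)$ are fitted by maximum
likelihood on the zero-truncated sample spectrum; crucially the number of
population classes is **not** assumed known but implied by the fit,
$\hat K = u / P(f \ge 1)$, and $\hat\lambda_3 = \hat K\, \hat p^{\hat r} / N$.
Convergence is declared only when the optimizer finishes within 500
iterations with gradient sup-norm below $10^{-6}$ on the unconstrained
scale; otherwise the result carries `converged = FALSE` and no estimate.
There is deliberately no fallback: the decision rule consumes the flag,
and on heavily singleton-dominated spectra (high-uniqueness populations)
the fit genuinely fails — an expected and informative outcome, not a bug.

**Zayatz** (`estimate_zayatz`). Model-free plug-in: with exact
hypergeometric subsampling probabilities
$P(f{=}1 \mid F{=}j) = j\binom{N-j}{n-1}/\binom{N}{n}$ and the observed
sample class-size distribution standing in for the population's,

$$\hat P(F{=}1 \mid f{=}1) =
  \frac{P(f{=}1\mid F{=}1)\, s_1}{\sum_j P(f{=}1\mid F{=}j)\, s_j},
\qquad \hat\lambda_3 = \frac{u_1 \hat P(F{=}1\mid f{=}1)}{\pi N},$$

where $s_j$ is the share of sample classes of size $j$. The exact
hypergeometric (rather than its binomial approximation) is used because
$N$ is known from the context; it makes the estimator exactly
$\lambda_3$ at $\pi = 1$ and lets toy cases be checked by exact
arithmetic.

**mu-argus** (`estimate_mu_argus`). The Benedetti–Franconi individual
risk model takes $P(F{=}k \mid f) = \binom{k-1}{f-1}\pi^f(1-\pi)^{k-f}$,
a negative-binomial posterior with the sampling fraction as parameter.
Extended to population uniqueness exactly as for Zayatz — sum the
posterior singleton probability over sample uniques and rescale by
$1/(\pi N)$. Since $P(F{=}1 \mid f{=}1) = \pi$, the extension collapses
analytically to $u_1/N$; the implementation evaluates the posterior
rather than hard-coding the collapsed form, and a test re-derives the
equality independently. Because $u_1/N \le \pi$, the estimator severely
underestimates high uniqueness at small sampling fractions — consistent
with it being the weakest of the four and excluded from the decision
rule.

## The E1 decision rule

No single estimator wins everywhere, so `e1()` selects among three:

```
If pi <= 0.1 then  E1 = Pitman
Else if SNB converges then
    if Est(SNB) > Est(Zayatz) then E1 = Zayatz else E1 = SNB
Else  E1 = Zayatz
```

The boundary is inclusive and computed at full precision from $n/N$; the
SNB/Zayatz comparison is strict, so a tie keeps SNB. The returned
estimate is bit-identical to the chosen component's, and mu-argus is
never evaluated. If the chosen component itself failed (Pitman can fail
at small $\pi$), the failed result is returned with its trace — the rule
text defines no further fallback and none is invented.

## The Monte Carlo evaluation harness

`run_study()` treats each supplied population as ground truth, draws
seeded record-level SRSWOR samples (replicate $r$ uses seed
`base_seed + r`, so every estimator sees the identical sample — a paired
design that removes sampling noise from estimator contrasts), and
summarizes each (population, fraction, estimator) study point by the
median and inter-quartile range of the relative bias
$(\hat\lambda_3 - \lambda_3)/\lambda_3$. The relative (not absolute)
error is summarized because acceptable uniqueness thresholds are small
(0.05–0.2), where a fixed absolute error matters much more; the median
(not MSE) is used because occasional extreme estimates would dominate a
squared-error summary. Non-converged runs are excluded from the
median/IQR and reported through an explicit convergence rate — exclusion
plus an auditable rate is a choice of this package, not a claim about how
any earlier study handled failures. IQR uses linear-interpolation
(type 7) quantiles; conventions differ, so the choice is fixed and
documented. The default grid is the sampling fractions
0.01, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9, three uniqueness tiers, four
estimators (84 study points for a three-tier data set) and 1000
replicates, with `runs` reducible for desk-scale checks.

## Synthetic populations

Because realistic registries cannot ship with a package, two seeded
generators make everything testable:

* `generate_crp_population()` draws class sizes by the sequential
  two-parameter Chinese restaurant process — the exact partition law of
  the Pitman model — and is the oracle substrate for the Pitman
  estimator. The loop is sequential by nature and implemented in C++
  against R's RNG.
* `generate_qi_population()` draws demographic-style columns (age, sex,
  code prefixes, dates) independently from declared marginals. The
  default marginals are deliberately skewed (Zipf-like code letters, a
  declining age pyramid): real demographic marginals are never uniform,
  and their skew is what produces the few large equivalence classes and
  long class-size tails seen in real registries. Columns are drawn
  independently — no correlation structure is modelled, which mainly
  understates how concentrated real data are. Uniqueness tiers (low
  < 10%, medium 10–50%, high > 50% of records unique) are reached by
  walking a generalization ladder (`tune_to_tier()`), exactly how tiered
  versions of a real data set are produced in practice; unreachable tiers
  are reported, not fabricated.

Ground truth everywhere is the **realized** population's $\lambda_3$,
computed from its class sizes — not the superpopulation expectation.

What passing tests on these populations do *not* show: behavior under
correlated quasi-identifiers, data-quality problems (duplicates, errors),
or non-uniform sampling designs. Exact matching is assumed throughout,
which errs conservative.

## Numerical choices and degenerate inputs

* Sample size from a fraction: `round(pi * N)`, minimum 1.
* Missing quasi-identifier values are an ordinary category by default
  (configurable to drop records).
* Pitman: $\theta$ is parameterized as $e^{\phi} - \alpha$ to keep
  $\theta > -\alpha$ for any $\alpha$ in the box; an all-singleton sample
  drives $\alpha$ to its upper boundary, where the fit is reported
  converged with $\alpha$ clamped at $1 - 10^{-6}$ and a boundary flag.
  A one-class sample gives $\hat\lambda_3 \le 1/N$.
* Both likelihood fits finish with a damped-Newton polish on the
  analytic gradient: near-flat ridges can stall quasi-Newton methods on
  function-value change before the gradient criterion is met.
* Estimates outside $[0,1]$ are clamped with an explicit diagnostic flag;
  clamping is never silent.
* All likelihood and hypergeometric computations run in log space via
  `lgamma`/`dhyper`/`dnbinom`.
* Seeded helpers save and restore the caller's RNG state, so library
  calls never perturb user simulations.

## Desk-scale problem sizes

The shipped tests validate the estimators at sizes a reviewer can run on
one CPU: CRP oracles with 10,000–20,000 draws at $N$ = 1000–2000,
parameter recovery and SNB self-consistency over 200 seeded replicates,
the sampling-consistency of $\lambda_2$ over 1000 draws per fraction at
$N = 2000$, and the qualitative bias-versus-fraction trend on a
three-tier $N = 5000$ synthetic study with 100 replicates per study
point. These sizes were chosen as the package's own test design; the
harness itself defaults to the full 1000 replicates.

## Known limitations

* The estimators assume simple random (record-wise, equal-probability)
  sampling of the disclosed data set from the population.
* The mu-argus extension is included for completeness and comparison; it
  is not part of the decision rule and should not be used alone.
* SNB convergence degrades as spectra approach all-singletons; users
  should expect and handle `converged = FALSE` (the E1 rule does).
* The generalization ladder is user-supplied; no optimal
  generalization/suppression search is attempted.
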