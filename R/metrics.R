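# Exact uniqueness risk metrics, computable when a population registry
# (e.g. a voter list) is available alongside the disclosed sample.

# Match sample classes to population classes; errors if the sample is not
# contained in the population class-wise.
match_classes <- function(pop, sample) {
  idx <- match(sample$keys, pop$keys)
  if (anyNA(idx)) {
    stop("containment violation: ", sum(is.na(idx)),
         " sample class(es) absent from the population", call. = FALSE)
  }
  if (any(sample$counts > pop$counts[idx])) {
    stop("containment violation: sample class larger than its population class",
         call. = FALSE)
  }
  idx
}

#' Conditional uniqueness risk (lambda 1)
#'
#' The probability that a record is unique in the population given that it
#' is unique in the disclosed sample: the share of sample uniques that are
#' also population uniques.  Undefined (returned as `NA`) when the sample
#' has no unique records, since the conditioning event is empty.
#'
#' @param pop Population equivalence classes (`eq_classes`).
#' @param sample Sample equivalence classes, contained in `pop` class-wise.
#' @return A number in \[0, 1\], or `NA_real_` when the sample has no uniques.
#' @seealso [lambda2()], [lambda3()]
#' @export
lambda1 <- function(pop, sample) {
  idx <- match_classes(pop, sample)
  su <- sample$counts == 1L
  if (!any(su)) return(NA_real_)
  sum(su & pop$counts[idx] == 1L) / sum(su)
}

#' Data-set uniqueness risk (lambda 2)
#'
#' The proportion of all disclosed records that are unique in both the
#' sample and the population — the share of the data set actually at risk
#' of certain re-identification.  Zero when the sample has no uniques.
#'
#' @inheritParams lambda1
#' @return A number in \[0, 1\].
#' @export
lambda2 <- function(pop, sample) {
  idx <- match_classes(pop, sample)
  su <- sample$counts == 1L
  sum(su & pop$counts[idx] == 1L) / sample$total
}

#' Population uniqueness (lambda 3)
#'
#' The proportion of records in the population that are unique on the
#' quasi-identifiers.  This is the quantity the sample-based estimators
#' target.
#'
#' @param pop Population equivalence classes (`eq_classes`).
#' @return A number in \[0, 1\].
#' @export
lambda3 <- function(pop) {
  sum(pop$counts == 1L) / pop$total
}

#' Exact risk metrics for a sample / population pair
#'
#' Computes all three uniqueness metrics plus the naive matching rate (the
#' share of sample records that are sample-unique, i.e. the rate an
#' adversary would be assumed to achieve if every sample unique matched).
#'
#' @inheritParams lambda1
#' @return An object of class `risk_metrics`: a list with `lambda1`,
#'   `lambda2`, `lambda3`, `naive_rate`, `n`, `N` and the class counts.
#' @export
risk_metrics <- function(pop, sample) {
  structure(
    list(lambda1 = lambda1(pop, sample),
         lambda2 = lambda2(pop, sample),
         lambda3 = lambda3(pop),
         naive_rate = sum(sample$counts == 1L) / sample$total,
         n = sample$total, N = pop$total,
         sample_uniques = sum(sample$counts == 1L),
         population_uniques = sum(pop$counts == 1L)),
    class = "risk_metrics"
  )
}

#' @export
print.risk_metrics <- function(x, digits = 2L, ...) {
  cat("Re-identification risk (exact, population file available)\n")
  cat(sprintf("  n = %d sample records, N = %d population records (pi = %.4g)\n",
              x$n, x$N, x$n / x$N))
  l1 <- if (is.na(x$lambda1)) "undefined (no sample uniques)" else
    sprintf("%.*f", digits, x$lambda1)
  cat(sprintf("  lambda1 (P[pop unique | sample unique]) = %s\n", l1))
  cat(sprintf("  lambda2 (share of data set at risk)     = %.*f\n", digits, x$lambda2))
  cat(sprintf("  lambda3 (population uniqueness)         = %.*f\n", digits, x$lambda3))
  cat(sprintf("  naive all-uniques-match rate            = %.0f%%\n",
              100 * x$naive_rate))
  invisible(x)
}
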