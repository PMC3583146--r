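# Practitioner workflow: estimate re-identification risk from a disclosed
# sample (assess), compute it exactly when a population registry is
# available (truth), and evaluate the estimators on a population by Monte
# Carlo (evaluate).  These functions back the command-line tool.

as_microdata_input <- function(x, qi = NULL, rules = list()) {
  md <- if (inherits(x, "microdata")) {
    if (!is.null(qi)) microdata(as.data.frame(x), qi = qi) else x
  } else if (is.character(x) && length(x) == 1L) {
    read_microdata(x, qi = qi)
  } else if (is.data.frame(x)) {
    microdata(x, qi = if (is.null(qi)) names(x) else qi)
  } else {
    stop("expected a microdata object, data frame, or CSV path", call. = FALSE)
  }
  if (length(rules) > 0L) md <- generalize(md, rules) else md
}

#' Assess re-identification risk from a disclosed sample
#'
#' The estimate-and-compare step of a disclosure-control workflow: computes
#' all four population-uniqueness estimates from the sample's frequency
#' spectrum, applies the E1 decision rule, and compares the E1 estimate
#' against an acceptability threshold.  Common threshold precedents are
#' 0.05 (public release) and 0.20 (research use).
#'
#' Exactly one of `N` (preferred) or `sampling_fraction` must be supplied;
#' the other is derived and echoed in the report.
#'
#' @param data A [microdata] object, data frame, or CSV path.
#' @param qi Quasi-identifier column names (defaults to all columns).
#' @param N Population size.
#' @param sampling_fraction Sampling fraction pi in (0, 1\].
#' @param threshold Acceptable population-uniqueness threshold in \[0, 1\];
#'   default 0.20.
#' @param rules Optional generalization rules applied before assessment.
#' @return An object of class `risk_assessment` containing the inputs
#'   summary, all four estimator results, the E1 result with its decision
#'   trace, and the threshold decision (`"below_threshold"` /
#'   `"above_threshold"`, based on the E1 estimate).
#' @examples
#' pop <- generate_qi_population(list(sex = qi_categorical(c("M", "F")),
#'                                    dob = qi_date("1980-01-01", "1999-12-31")),
#'                               N = 2000, seed = 11)
#' smp <- srswor_sample(pop, 0.3, seed = 12)
#' assess_risk(smp, N = 2000, threshold = 0.2)
#' @export
assess_risk <- function(data, qi = NULL, N = NULL, sampling_fraction = NULL,
                        threshold = 0.20, rules = list()) {
  md <- as_microdata_input(data, qi, rules)
  n <- nrow(md)
  if (is.null(N) == is.null(sampling_fraction)) {
    stop("supply exactly one of `N` or `sampling_fraction`", call. = FALSE)
  }
  if (is.null(N)) {
    if (sampling_fraction <= 0 || sampling_fraction > 1) {
      stop("`sampling_fraction` must lie in (0, 1]", call. = FALSE)
    }
    N <- as.integer(round(n / sampling_fraction))
  }
  if (N < n) stop("population size N (", N, ") is smaller than the sample (", n, ")",
                  call. = FALSE)
  if (!is.null(threshold) && (threshold < 0 || threshold > 1)) {
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  }
  ctx <- sampling_context(n, N)
  sp <- spectrum_of(build_equivalence_classes(md))
  estimates <- estimate_all(sp, ctx)
  rule <- e1(sp, ctx)
  decision <- if (is.null(threshold) || is.na(rule$estimate$lambda3_hat)) NA_character_
              else if (rule$estimate$lambda3_hat > threshold) "above_threshold"
              else "below_threshold"
  structure(
    list(n = n, N = N, pi = ctx$pi,
         quasi_identifiers = qi_names(md),
         sample_uniques = spectrum_count(sp, 1L),
         estimates = estimates,
         e1 = rule,
         threshold = threshold,
         decision = decision,
         version = as.character(utils::packageVersion("uniqrisk"))),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("Re-identification risk assessment (population uniqueness)\n")
  cat(sprintf("  n = %d, N = %d, pi = %.4g; quasi-identifiers: %s\n",
              x$n, x$N, x$pi, paste(x$quasi_identifiers, collapse = ", ")))
  cat(sprintf("  sample uniques: %d (%.1f%% of the sample)\n",
              x$sample_uniques, 100 * x$sample_uniques / x$n))
  for (est in x$estimates) {
    val <- if (is.na(est$lambda3_hat)) "failed to converge"
           else sprintf("%.4f", est$lambda3_hat)
    cat(sprintf("  %-9s lambda3_hat = %s\n", est$estimator, val))
  }
  e1v <- if (is.na(x$e1$estimate$lambda3_hat)) "unavailable"
         else sprintf("%.4f", x$e1$estimate$lambda3_hat)
  cat(sprintf("  E1 rule chose %s: lambda3_hat = %s\n", x$e1$chosen, e1v))
  if (!is.null(x$threshold)) {
    cat(sprintf("  threshold %.2f -> %s\n", x$threshold, x$decision))
  }
  invisible(x)
}

#' Serialize an assessment or metrics report as JSON text
#'
#' Writes a flat, machine-readable report: lambda values at full precision
#' plus 2-decimal display values, the decision trace, configuration and
#' tool version.  The report round-trips through [jsonlite::fromJSON()].
#'
#' @param x A `risk_assessment` or `risk_metrics` object.
#' @param path Optional output path; when omitted the JSON text is returned.
#' @return The JSON text, invisibly when written to `path`.
#' @export
write_report <- function(x, path = NULL) {
  rep <- if (inherits(x, "risk_assessment")) {
    list(
      report = "risk_assessment",
      version = x$version,
      inputs = list(n = x$n, N = x$N, pi = x$pi,
                    quasi_identifiers = x$quasi_identifiers),
      estimates = lapply(x$estimates, function(e) list(
        estimator = e$estimator,
        lambda3_hat = e$lambda3_hat,
        lambda3_hat_display = round(e$lambda3_hat, 2L),
        converged = e$converged,
        params = e$params)),
      e1 = list(chosen = x$e1$chosen,
                lambda3_hat = x$e1$estimate$lambda3_hat,
                lambda3_hat_display = round(x$e1$estimate$lambda3_hat, 2L),
                converged = x$e1$estimate$converged,
                branch_path = x$e1$trace$branch_path,
                component_estimates = x$e1$trace$component_estimates),
      threshold = x$threshold,
      decision = x$decision
    )
  } else if (inherits(x, "risk_metrics")) {
    list(
      report = "risk_metrics",
      version = as.character(utils::packageVersion("uniqrisk")),
      inputs = list(n = x$n, N = x$N, pi = x$n / x$N),
      lambda1 = x$lambda1, lambda1_display = round(x$lambda1, 2L),
      lambda2 = x$lambda2, lambda2_display = round(x$lambda2, 2L),
      lambda3 = x$lambda3, lambda3_display = round(x$lambda3, 2L),
      naive_rate = x$naive_rate,
      sample_uniques = x$sample_uniques,
      population_uniques = x$population_uniques
    )
  } else {
    stop("`x` must be a risk_assessment or risk_metrics object", call. = FALSE)
  }
  json <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Exact risk metrics from sample and population files
#'
#' Computes the exact uniqueness metrics when the population registry is
#' available: lambda1 (conditional), lambda2 (data-set risk) and lambda3
#' (population uniqueness), plus the naive all-uniques-match rate.  The
#' sample must be contained in the population class-wise; a violation is a
#' linkage error.
#'
#' @param sample,population [microdata] objects, data frames, or CSV paths
#'   sharing the declared quasi-identifiers.
#' @param qi Quasi-identifier column names (defaults to all of the sample's
#'   columns).
#' @param rules Optional generalization rules applied to both tables.
#' @return A [risk_metrics] object.
#' @export
true_risk <- function(sample, population, qi = NULL, rules = list()) {
  smp <- as_microdata_input(sample, qi, rules)
  pop <- as_microdata_input(population, if (is.null(qi)) qi_names(smp) else qi, rules)
  risk_metrics(build_equivalence_classes(pop), build_equivalence_classes(smp))
}

#' Evaluate the estimators on population data by Monte Carlo
#'
#' Drives [run_study()] on one or more populations (CSV paths or
#' [microdata] objects) and optionally writes the per-replicate and summary
#' study tables.
#'
#' @param populations Named list of populations ([microdata] or CSV paths),
#'   e.g. tiered versions of one data set.
#' @param qi Quasi-identifier columns (for CSV inputs).
#' @param grid A [study_grid()].
#' @param runs_file,summary_file Optional output paths (tab-separated).
#' @return A `uniq_study` object.
#' @export
evaluate_estimators <- function(populations, qi = NULL, grid = study_grid(),
                                runs_file = NULL, summary_file = NULL) {
  pops <- lapply(populations, as_microdata_input, qi = qi)
  study <- run_study(pops, grid)
  export_study_table(study, runs_file, summary_file)
  study
}
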