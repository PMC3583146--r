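# Monte Carlo evaluation harness: treat each supplied data set as a
# population, draw repeated simple random samples over a grid of sampling
# fractions, run every estimator on each sample, and summarize accuracy by
# the median and inter-quartile range of the relative bias.

#' Relative bias of an estimate
#'
#' `(estimate - truth) / truth`, the signed relative error.  Undefined
#' (`NA`) when the truth is zero: a zero-uniqueness population is outside
#' the metric's domain.
#'
#' @param estimate Estimated population uniqueness.
#' @param truth True population uniqueness (> 0).
#' @return The signed relative bias, or `NA_real_`.
#' @export
relative_bias <- function(estimate, truth) {
  out <- (estimate - truth) / truth
  out[rep_len(truth <= 0, length(out))] <- NA_real_
  out
}

#' Classify a population's uniqueness tier
#'
#' Tiers follow the conventional cut points: below 10% of records unique is
#' `low`, 10%--50% is `medium`, above 50% is `high`.
#'
#' @param lambda3 Population uniqueness in \[0, 1\].
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
classify_uniqueness_tier <- function(lambda3) {
  stopifnot(all(lambda3 >= 0 & lambda3 <= 1))
  ifelse(lambda3 < 0.10, "low", ifelse(lambda3 <= 0.50, "medium", "high"))
}

#' Study grid for the evaluation harness
#'
#' @param sampling_fractions Ordered sampling fractions; the default grid is
#'   `c(0.01, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @param estimators Estimator names drawn from
#'   `c("pitman", "snb", "zayatz", "mu_argus", "e1")`.
#' @param runs Replicates per study point (default 1000; reduce for smoke
#'   runs).
#' @param base_seed Base seed; replicate r uses seed `base_seed + r` so all
#'   estimators see the identical sample.
#' @return A `study_grid` object.
#' @export
study_grid <- function(sampling_fractions = c(0.01, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9),
                       estimators = c("pitman", "snb", "zayatz", "mu_argus"),
                       runs = 1000L, base_seed = 1L) {
  stopifnot(all(sampling_fractions > 0 & sampling_fractions <= 1), runs >= 1)
  structure(list(sampling_fractions = sampling_fractions,
                 estimators = estimators,
                 runs = as.integer(runs),
                 base_seed = as.integer(base_seed)),
            class = "study_grid")
}

resolve_estimators <- function(names, extra = list()) {
  builtin <- list(
    pitman = estimate_pitman, snb = estimate_snb,
    zayatz = estimate_zayatz, mu_argus = estimate_mu_argus,
    e1 = function(sp, ctx) e1(sp, ctx)$estimate)
  registry <- utils::modifyList(builtin, extra)
  missing <- setdiff(names, names(registry))
  if (length(missing) > 0L) {
    stop("unknown estimator(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  registry[names]
}

# Interpolation quantiles (type 7), the documented IQR convention.
iqr_linear <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Run the Monte Carlo estimator-evaluation study
#'
#' For each supplied population, each sampling fraction and each replicate,
#' a seeded SRSWOR sample is drawn once and every estimator is applied to
#' its frequency spectrum (paired sampling, so estimator comparisons are
#' not confounded by sampling noise).  Per study point (population x
#' fraction x estimator) the harness records every run's relative bias and
#' summarizes the converged runs by median and inter-quartile range;
#' non-converged runs are excluded from the summaries and reported through
#' the convergence rate.
#'
#' @param populations A named list of [microdata] populations (for example
#'   the low / medium / high uniqueness versions of a data set).  Each
#'   population's true uniqueness is computed exactly from its records.
#' @param grid A [study_grid()].
#' @param extra_estimators Optional named list of custom estimator functions
#'   `function(sp, ctx) -> uniq_estimate`, allowing oracle or constant
#'   estimators to be plugged into the harness; names referenced from
#'   `grid$estimators` resolve here first, then to the built-ins.
#' @param quiet Suppress progress messages.
#' @return An object of class `uniq_study`: list with `points` (one summary
#'   row per study point), `runs` (one row per study point x replicate) and
#'   the grid.
#' @export
run_study <- function(populations, grid = study_grid(), extra_estimators = list(),
                      quiet = TRUE) {
  stopifnot(is.list(populations), length(populations) > 0L)
  if (is.null(names(populations)) || any(names(populations) == "")) {
    names(populations) <- paste0("pop", seq_along(populations))
  }

  estimator_fns <- resolve_estimators(grid$estimators, extra_estimators)

  point_rows <- list()
  run_rows <- list()

  for (pop_id in names(populations)) {
    pop <- populations[[pop_id]]
    stopifnot(inherits(pop, "microdata"))
    pop_ect <- build_equivalence_classes(pop)
    truth <- lambda3(pop_ect)
    tier <- classify_uniqueness_tier(truth)
    N <- nrow(pop)
    if (truth == 0) {
      warning("population '", pop_id, "' has zero uniqueness; relative bias ",
              "is undefined there", call. = FALSE)
    }

    for (frac in grid$sampling_fractions) {
      if (!quiet) message(sprintf("population %s (tier %s), pi = %g", pop_id, tier, frac))
      est_mat <- matrix(NA_real_, nrow = grid$runs, ncol = length(grid$estimators),
                        dimnames = list(NULL, grid$estimators))
      conv_mat <- matrix(FALSE, nrow = grid$runs, ncol = length(grid$estimators),
                         dimnames = list(NULL, grid$estimators))
      for (r in seq_len(grid$runs)) {
        seed <- grid$base_seed + r
        smp <- srswor_sample(pop, frac, seed)
        sp <- spectrum_of(build_equivalence_classes(smp))
        ctx <- sampling_context(nrow(smp), N)
        for (est_name in grid$estimators) {
          res <- tryCatch(estimator_fns[[est_name]](sp, ctx),
                          error = function(e) NULL)
          if (!is.null(res) && res$converged && !is.na(res$lambda3_hat)) {
            est_mat[r, est_name] <- res$lambda3_hat
            conv_mat[r, est_name] <- TRUE
          }
        }
      }
      for (est_name in grid$estimators) {
        rb <- relative_bias(est_mat[, est_name], truth)
        ok <- conv_mat[, est_name] & !is.na(rb)
        point_rows[[length(point_rows) + 1L]] <- data.frame(
          dataset_id = pop_id, uniqueness_tier = tier,
          sampling_fraction = frac, estimator = est_name,
          true_lambda3 = truth, n_runs = grid$runs,
          convergence_rate = mean(conv_mat[, est_name]),
          median_relative_bias = if (any(ok)) stats::median(rb[ok]) else NA_real_,
          iqr_relative_bias = if (any(ok)) iqr_linear(rb[ok]) else NA_real_,
          stringsAsFactors = FALSE)
        run_rows[[length(run_rows) + 1L]] <- data.frame(
          dataset_id = pop_id, uniqueness_tier = tier,
          sampling_fraction = frac, estimator = est_name,
          replicate = seq_len(grid$runs),
          seed = grid$base_seed + seq_len(grid$runs),
          estimate = est_mat[, est_name],
          converged = conv_mat[, est_name],
          relative_bias = rb,
          stringsAsFactors = FALSE)
      }
    }
  }

  structure(list(points = do.call(rbind, point_rows),
                 runs = do.call(rbind, run_rows),
                 grid = grid),
            class = "uniq_study")
}

#' @export
print.uniq_study <- function(x, ...) {
  cat("Monte Carlo uniqueness-estimation study:",
      nrow(x$points), "study points,", x$grid$runs, "runs each\n")
  print(utils::head(x$points, 12L), row.names = FALSE)
  if (nrow(x$points) > 12L) cat("...\n")
  invisible(x)
}

#' Export study tables
#'
#' Writes (or returns) the per-replicate study-point table — one row per
#' (study point, replicate), suitable for downstream modelling such as a
#' regression tree over relative bias — and the summary table (fraction x
#' estimator -> median and IQR of relative bias, convergence rate).
#'
#' @param study A `uniq_study` from [run_study()].
#' @param runs_file,summary_file Optional paths; when given, tables are
#'   written as tab-separated text with a header row.
#' @return Invisibly, a list with `runs` and `summary` data frames.
#' @export
export_study_table <- function(study, runs_file = NULL, summary_file = NULL) {
  stopifnot(inherits(study, "uniq_study"))
  out <- list(runs = study$runs, summary = study$points)
  if (!is.null(runs_file)) {
    utils::write.table(out$runs, runs_file, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(summary_file)) {
    utils::write.table(out$summary, summary_file, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}
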