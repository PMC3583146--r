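# Seeded synthetic populations with controllable uniqueness, so that the
# estimators and the evaluation harness are fully testable without access
# to confidential registries.

#' Generate a population from the Chinese-restaurant process
#'
#' Draws equivalence-class sizes for a population of `N` records by the
#' sequential two-parameter Chinese-restaurant process: record n+1 joins an
#' existing class of size s with probability `(s - alpha) / (n + theta)`
#' and founds a new class with probability `(theta + K alpha) / (n + theta)`.
#' This is the exact partition law of the Pitman model, making these
#' populations the oracle substrate for the Pitman estimator.
#'
#' The realized population's uniqueness (`lambda3` of the returned table)
#' is the ground truth used downstream — realization truth, not the
#' superpopulation expectation.
#'
#' @param N Population size (>= 1).
#' @param alpha Discount parameter in \[0, 1).
#' @param theta Concentration parameter, > -alpha.
#' @param seed Integer seed; the class-size multiset is deterministic
#'   given `(N, alpha, theta, seed)`.
#' @return An [eq_classes()] population table.
#' @export
generate_crp_population <- function(N, alpha, theta, seed) {
  sizes <- with_seed(seed, crp_class_sizes_cpp(as.integer(N), alpha, theta))
  eq_classes(sizes)
}

#' Quasi-identifier column schemas
#'
#' Column specifications for [generate_qi_population()], emulating the
#' demographic quasi-identifiers common in clinical data (age, sex, postal
#' prefix, admission or birth dates).  Values are drawn independently per
#' column from the stated marginal.
#'
#' @param min,max Integer age range (inclusive).
#' @param levels Category labels.
#' @param probs Optional category (or, for codes, per-position letter)
#'   probabilities; uniform when omitted.  For `qi_age()` the default is a
#'   gently declining age-pyramid weight, since real demographic marginals
#'   are never uniform and their skew is what produces the large
#'   equivalence classes seen in real registries.
#' @param alphabet Characters the code positions are drawn from.
#' @param length Code length.
#' @param start,end Date window (inclusive), drawn uniformly by day.
#' @return A `qi_column` specification.
#' @name qi-columns
NULL

#' @rdname qi-columns
#' @export
qi_age <- function(min = 0L, max = 90L, probs = NULL) {
  min <- as.integer(min); max <- as.integer(max)
  if (is.null(probs)) {
    ages <- seq(min, max)
    probs <- pmax(1 - ages / (max + 30), 0.05)
  }
  stopifnot(length(probs) == max - min + 1L)
  structure(list(kind = "age", min = min, max = max, probs = probs),
            class = "qi_column")
}

#' @rdname qi-columns
#' @export
qi_categorical <- function(levels, probs = NULL) {
  if (!is.null(probs)) stopifnot(length(probs) == length(levels))
  structure(list(kind = "categorical", levels = as.character(levels), probs = probs),
            class = "qi_column")
}

#' @rdname qi-columns
#' @export
qi_code <- function(alphabet = LETTERS, length = 3L, probs = NULL) {
  if (is.null(probs)) probs <- (1 / seq_along(alphabet))  # Zipf-like: a few
                                                          # dense areas dominate
  stopifnot(length(probs) == length(alphabet))
  structure(list(kind = "code", alphabet = as.character(alphabet),
                 length = as.integer(length), probs = probs / sum(probs)),
            class = "qi_column")
}

#' @rdname qi-columns
#' @export
qi_date <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(start <= end)
  structure(list(kind = "date", start = start, end = end), class = "qi_column")
}

draw_column <- function(spec, N) {
  switch(spec$kind,
    age = as.character(sample(seq(spec$min, spec$max), N, replace = TRUE,
                              prob = spec$probs)),
    categorical = sample(spec$levels, N, replace = TRUE, prob = spec$probs),
    code = {
      m <- matrix(sample(spec$alphabet, N * spec$length, replace = TRUE,
                         prob = spec$probs), nrow = N)
      apply(m, 1L, paste0, collapse = "")
    },
    date = {
      days <- as.integer(spec$end - spec$start)
      format(spec$start + sample.int(days + 1L, N, replace = TRUE) - 1L, "%Y-%m-%d")
    },
    stop("unknown column kind: ", spec$kind, call. = FALSE)
  )
}

#' Generate a demographic-style synthetic population
#'
#' Draws `N` records with independent columns from a quasi-identifier
#' schema (see [qi_age()] and friends).  Deterministic given the seed.
#' Columns are independent; no correlation structure is modelled.
#'
#' @param schema Named list of `qi_column` specifications; names become the
#'   quasi-identifier column names.
#' @param N Population size (>= 10).
#' @param seed Integer seed.
#' @return A [microdata] population.
#' @examples
#' pop <- generate_qi_population(
#'   list(sex = qi_categorical(c("M", "F")),
#'        dob = qi_date("1960-01-01", "1999-12-31")),
#'   N = 500, seed = 7)
#' lambda3(build_equivalence_classes(pop))
#' @export
generate_qi_population <- function(schema, N, seed) {
  if (!is.list(schema) || length(schema) < 1L) {
    stop("`schema` must be a non-empty named list of qi_column specs", call. = FALSE)
  }
  if (is.null(names(schema)) || any(names(schema) == "")) {
    stop("every schema column must be named", call. = FALSE)
  }
  N <- as.integer(N)
  if (N < 10L) stop("`N` must be at least 10", call. = FALSE)
  cols <- with_seed(seed, lapply(schema, draw_column, N = N))
  microdata(as.data.frame(cols, stringsAsFactors = FALSE,
                          check.names = FALSE),
            qi = names(schema))
}

#' Generalize a population to a target uniqueness tier
#'
#' Walks an ordered ladder of generalization rule sets (finest to
#' coarsest), recomputing the population uniqueness after each rung, and
#' returns the first version whose tier matches the target.  Mirrors the
#' practice of creating low / medium / high uniqueness versions of a data
#' set by generalizing its quasi-identifiers.  Some tiers can be genuinely
#' unreachable for a given data set; that outcome is reported, not raised.
#'
#' @param md A [microdata] population.
#' @param tier Target tier: `"low"`, `"medium"` or `"high"`.
#' @param ladder List of rule sets (each a list of `gen_rule`s), ordered
#'   finest to coarsest.  An empty rule set (`list()`) stands for the
#'   original table and is tried first implicitly.
#' @return A list with `reached` (logical), `table` (the qualifying
#'   [microdata], or `NULL`), `lambda3`, `tier_achieved` and `rung` (0 for
#'   the original table).
#' @export
tune_to_tier <- function(md, tier = c("low", "medium", "high"), ladder) {
  tier <- match.arg(tier)
  stopifnot(inherits(md, "microdata"), is.list(ladder))
  rungs <- c(list(list()), ladder)
  tried <- character(0)
  for (i in seq_along(rungs)) {
    g <- generalize(md, rungs[[i]])
    l3 <- lambda3(build_equivalence_classes(g))
    achieved <- classify_uniqueness_tier(l3)
    tried <- c(tried, achieved)
    if (achieved == tier) {
      return(list(reached = TRUE, table = g, lambda3 = l3,
                  tier_achieved = achieved, rung = i - 1L))
    }
  }
  list(reached = FALSE, table = NULL, lambda3 = NA_real_,
       tier_achieved = tried, rung = NA_integer_)
}

#' Three-tier synthetic study populations
#'
#' Builds low / medium / high uniqueness versions of one synthetic
#' demographic population by generalizing its date-of-birth column down a
#' day -> month -> year -> decade ladder, emulating how tiered versions of
#' a real data set are produced.  The default schema (sex, age, 2-letter
#' region code, date of birth over a 40-year window) reaches all three
#' tiers at the default size.
#'
#' @param N Population size.
#' @param seed Integer seed.
#' @return Named list of three [microdata] populations (`low`, `medium`,
#'   `high`); tiers that could not be reached are dropped with a warning.
#' @export
synthetic_study_populations <- function(N = 5000L, seed = 20120709L) {
  schema <- list(
    sex = qi_categorical(c("M", "F"), c(0.51, 0.49)),
    age = qi_age(0L, 90L),
    region = qi_code(LETTERS[1:6], 2L),
    dob = qi_date("1960-01-01", "1999-12-31")
  )
  base <- generate_qi_population(schema, N = N, seed = seed)
  ladder <- list(
    list(rule_date_precision("dob", "month")),
    list(rule_date_precision("dob", "year")),
    list(rule_date_precision("dob", "decade")),
    list(rule_date_precision("dob", "decade"), rule_bin("age", 10)),
    list(rule_date_precision("dob", "decade"), rule_bin("age", 30)),
    list(rule_date_precision("dob", "decade"), rule_bin("age", 30),
         rule_prefix("region", 1L))
  )
  out <- list()
  for (tier in c("low", "medium", "high")) {
    res <- tune_to_tier(base, tier, ladder)
    if (res$reached) out[[tier]] <- res$table
    else warning("tier '", tier, "' unreachable for this population", call. = FALSE)
  }
  out
}
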