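# Quasi-identifier generalization: coarsening a column so that more records
# fall into the same equivalence class (e.g. date of birth -> year of birth,
# six-character postal code -> three-character prefix).  Generalization can
# only merge classes, never split them.

#' Generalization rules
#'
#' Constructors for the three supported generalization rule kinds.
#'
#' * `rule_date_precision()` reduces a date column to `"month"` (`YYYY-MM`),
#'   `"year"` (`YYYY`) or `"decade"` (`floor(year / 10) * 10`); `"day"` is
#'   the identity.  Values are parsed as ISO-8601 by default, or with a
#'   caller-supplied `format` string.
#' * `rule_prefix()` truncates a string column to its first `k` characters
#'   (postal-code style).
#' * `rule_bin()` bins a numeric column into intervals of width `width`
#'   anchored at `origin`, labelled by the interval lower bound.
#'
#' @param column Name of the column the rule applies to.
#' @param precision One of `"day"`, `"month"`, `"year"`, `"decade"`.
#' @param format Optional date format string for [base::as.Date()]; the
#'   default parses ISO-8601 (`YYYY-MM-DD`).
#' @param on_error Policy for values that fail to parse under a date rule:
#'   `"fail"` (default) raises an error naming the offending values;
#'   `"pass"` leaves them verbatim.
#' @param k Number of leading characters to keep.
#' @param width Bin width (> 0).
#' @param origin Bin origin (default 0).
#' @return A `gen_rule` object.
#' @name generalization-rules
NULL

#' @rdname generalization-rules
#' @export
rule_date_precision <- function(column, precision = c("year", "month", "decade", "day"),
                                format = NULL, on_error = c("fail", "pass")) {
  precision <- match.arg(precision)
  structure(list(kind = "date", column = column, precision = precision,
                 format = format, on_error = match.arg(on_error)),
            class = "gen_rule")
}

#' @rdname generalization-rules
#' @export
rule_prefix <- function(column, k) {
  stopifnot(is.numeric(k), k >= 1)
  structure(list(kind = "prefix", column = column, k = as.integer(k)),
            class = "gen_rule")
}

#' @rdname generalization-rules
#' @export
rule_bin <- function(column, width, origin = 0) {
  stopifnot(is.numeric(width), width > 0)
  structure(list(kind = "bin", column = column, width = width, origin = origin),
            class = "gen_rule")
}

apply_rule <- function(values, rule) {
  switch(rule$kind,
    date = {
      v <- as.character(values)
      d <- if (is.null(rule$format)) as.Date(v, format = "%Y-%m-%d")
           else as.Date(v, format = rule$format)
      bad <- is.na(d) & !is.na(v)
      if (any(bad)) {
        if (rule$on_error == "fail") {
          stop("unparseable date value(s) in column '", rule$column, "': ",
               paste(utils::head(unique(v[bad]), 3L), collapse = ", "),
               call. = FALSE)
        }
      }
      out <- switch(rule$precision,
        day    = format(d, "%Y-%m-%d"),
        month  = format(d, "%Y-%m"),
        year   = format(d, "%Y"),
        decade = as.character(10L * (as.integer(format(d, "%Y")) %/% 10L))
      )
      out[bad] <- v[bad]   # only reachable under on_error = "pass"
      out[is.na(v)] <- NA_character_
      out
    },
    prefix = {
      v <- as.character(values)
      substr(v, 1L, rule$k)
    },
    bin = {
      x <- suppressWarnings(as.numeric(values))
      bad <- is.na(x) & !is.na(values)
      if (any(bad)) {
        stop("non-numeric value(s) in column '", rule$column,
             "' under a binning rule", call. = FALSE)
      }
      lo <- floor((x - rule$origin) / rule$width) * rule$width + rule$origin
      as.character(lo)
    },
    stop("unknown rule kind: ", rule$kind, call. = FALSE)
  )
}

#' Apply generalization rules to microdata
#'
#' Applies each rule to its column independently; record count and column
#' order are unchanged.  Because generalization maps each original value to
#' one coarser value, it can only merge equivalence classes: the number of
#' classes never increases and no class shrinks.
#'
#' @param md A [microdata] object.
#' @param rules A list of `gen_rule` objects (see [rule_date_precision()]);
#'   an empty list is the identity.
#' @return A [microdata] object with the same records, generalized.
#' @examples
#' md <- microdata(data.frame(dob = c("1962-07-04", "1962-11-20"),
#'                            postal = c("N3E 6Y4", "K1H 8L1")))
#' g <- generalize(md, list(rule_date_precision("dob", "year"),
#'                          rule_prefix("postal", 3)))
#' g$dob     # "1962" "1962"
#' g$postal  # "N3E" "K1H"
#' @export
generalize <- function(md, rules) {
  stopifnot(inherits(md, "microdata"))
  if (inherits(rules, "gen_rule")) rules <- list(rules)
  df <- as.data.frame(md)
  for (rule in rules) {
    if (!inherits(rule, "gen_rule")) stop("rules must be gen_rule objects", call. = FALSE)
    if (!rule$column %in% names(df)) {
      stop("generalization rule references unknown column '", rule$column, "'",
           call. = FALSE)
    }
    df[[rule$column]] <- apply_rule(df[[rule$column]], rule)
  }
  microdata(df, qi = qi_names(md))
}
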