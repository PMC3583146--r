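#' Microdata restricted to quasi-identifiers
#'
#' A `microdata` object is the unit an adversary would match on: the records
#' of a data set projected onto the declared quasi-identifiers.  Values are
#' compared by exact equality after parsing (and optional generalization);
#' there is no fuzzy matching.
#'
#' @param data A data frame containing at least the quasi-identifier columns.
#' @param qi Character vector of quasi-identifier column names, in order.
#' @param na_action How to treat missing quasi-identifier values: `"category"`
#'   (the default) keeps `NA` as an ordinary category of its own;
#'   `"drop"` removes records with any missing quasi-identifier.
#'
#' @return An object of class `microdata`: a data frame with the
#'   quasi-identifier columns only, plus a `qi` attribute.
#' @examples
#' md <- microdata(data.frame(age = c(17, 17, 18), sex = c("M", "F", "M")),
#'                 qi = c("age", "sex"))
#' nrow(md)
#' @export
microdata <- function(data, qi = names(data), na_action = c("category", "drop")) {
  na_action <- match.arg(na_action)
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  if (length(qi) < 1L) stop("at least one quasi-identifier is required", call. = FALSE)
  missing_qi <- setdiff(qi, names(data))
  if (length(missing_qi) > 0L) {
    stop("quasi-identifier column(s) not found: ",
         paste(missing_qi, collapse = ", "), call. = FALSE)
  }
  out <- data[, qi, drop = FALSE]
  rownames(out) <- NULL
  if (na_action == "drop") {
    keep <- stats::complete.cases(out)
    out <- out[keep, , drop = FALSE]
  }
  if (nrow(out) < 1L) stop("microdata must contain at least one record", call. = FALSE)
  structure(out, qi = qi, class = c("microdata", "data.frame"))
}

#' @export
print.microdata <- function(x, ...) {
  cat("Microdata:", nrow(x), "records,", length(attr(x, "qi")),
      "quasi-identifiers (", paste(attr(x, "qi"), collapse = ", "), ")\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more records\n")
  invisible(x)
}

#' Quasi-identifier names of a microdata object
#' @param x A `microdata` object.
#' @return Character vector of quasi-identifier column names.
#' @export
qi_names <- function(x) attr(x, "qi")

#' Read microdata from a CSV file
#'
#' Reads an RFC-4180 CSV file (header row required) and restricts it to the
#' declared quasi-identifiers.  All columns are read as character so that
#' values behave as opaque atoms; generalization rules parse dates and
#' numbers explicitly when applied.
#'
#' @param path Path to a CSV file with a header row.
#' @param qi Character vector of quasi-identifier column names; defaults to
#'   all columns.
#' @inheritParams microdata
#' @return A `microdata` object.
#' @export
read_microdata <- function(path, qi = NULL, na_action = "category") {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (is.null(qi)) qi <- names(df)
  microdata(df, qi = qi, na_action = na_action)
}

#' Write microdata to a CSV file
#' @param x A `microdata` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
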