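# Equivalence classes and the frequency-of-frequencies spectrum.
#
# An equivalence class is the set of records sharing identical values on all
# quasi-identifiers; its size is f_i in a sample and F_i in a population.
# The spectrum (number of classes of each size) is the sufficient statistic
# consumed by every uniqueness estimator.

# Unit separator keeps multi-column keys unambiguous even if values contain
# commas or spaces.
.KEY_SEP <- "\x1f"

record_keys <- function(md, qi = qi_names(md)) {
  cols <- lapply(qi, function(nm) {
    v <- md[[nm]]
    v <- as.character(v)
    v[is.na(v)] <- "\x1eNA"
    v
  })
  do.call(paste, c(cols, sep = .KEY_SEP))
}

#' Build equivalence classes from microdata
#'
#' Groups records by exact equality on the quasi-identifiers (or a subset)
#' and returns the table of class counts.
#'
#' @param md A [microdata] object.
#' @param qi_subset Quasi-identifiers to group on; defaults to all declared
#'   quasi-identifiers.
#' @return An object of class `eq_classes` with components `keys` (one
#'   encoded key per class), `counts` (class sizes, each >= 1), `total`
#'   (number of records, n or N) and `num_classes` (u or K).
#' @examples
#' md <- microdata(data.frame(age = c(17, 17, 17, 17, 17, 18),
#'                            sex = c("M", "M", "M", "F", "F", "M")))
#' ec <- build_equivalence_classes(md)
#' sort(ec$counts, decreasing = TRUE)  # 3 2 1
#' @export
build_equivalence_classes <- function(md, qi_subset = NULL) {
  if (!inherits(md, "microdata")) stop("`md` must be a microdata object", call. = FALSE)
  qi <- qi_names(md)
  if (is.null(qi_subset)) qi_subset <- qi
  if (length(qi_subset) < 1L) stop("`qi_subset` must name at least one column", call. = FALSE)
  unknown <- setdiff(qi_subset, qi)
  if (length(unknown) > 0L) {
    stop("unknown quasi-identifier(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keys <- record_keys(md, qi_subset)
  tab <- table(keys)
  eq_classes(keys = names(tab), counts = as.integer(tab))
}

#' Construct an equivalence-class table directly
#'
#' Low-level constructor used when class counts are produced by code (for
#' example, by the synthetic population generators) rather than tabulated
#' from records.
#'
#' @param counts Integer vector of class sizes, all >= 1.
#' @param keys Optional character vector of class keys (unique, same length
#'   as `counts`); synthetic keys `c1, c2, ...` are generated when omitted.
#' @return An `eq_classes` object.
#' @export
eq_classes <- function(counts, keys = NULL) {
  counts <- as.integer(counts)
  if (length(counts) < 1L || any(is.na(counts)) || any(counts < 1L)) {
    stop("class counts must be positive integers", call. = FALSE)
  }
  if (is.null(keys)) keys <- paste0("c", seq_along(counts))
  if (anyDuplicated(keys)) stop("class keys must be unique", call. = FALSE)
  if (length(keys) != length(counts)) stop("keys and counts lengths differ", call. = FALSE)
  structure(
    list(keys = as.character(keys), counts = counts,
         total = sum(counts), num_classes = length(counts)),
    class = "eq_classes"
  )
}

#' @export
print.eq_classes <- function(x, ...) {
  cat("Equivalence classes:", x$num_classes, "classes over", x$total, "records\n")
  cat("  singletons:", sum(x$counts == 1L),
      " largest class:", max(x$counts), "\n")
  invisible(x)
}

#' Frequency spectrum (frequency of frequencies)
#'
#' Collapses an equivalence-class table to the number of classes of each
#' size.  The spectrum, together with the sample and population sizes, is a
#' sufficient statistic for all the uniqueness estimators: permuting records
#' or relabelling classes never changes an estimate.
#'
#' @param x An `eq_classes` object, or an integer vector of class sizes.
#' @return An object of class `freq_spectrum` with components `sizes`
#'   (distinct class sizes j), `counts` (number of classes of size j),
#'   `total` (sum of j * count) and `num_classes` (sum of counts).
#' @examples
#' sp <- spectrum_of(eq_classes(c(3, 2, 1, 1)))
#' sp$sizes   # 1 2 3
#' sp$counts  # 2 1 1
#' @export
spectrum_of <- function(x) {
  if (inherits(x, "eq_classes")) counts <- x$counts
  else counts <- as.integer(x)
  if (length(counts) < 1L || any(counts < 1L)) {
    stop("class sizes must be positive", call. = FALSE)
  }
  tab <- table(counts)
  sizes <- as.integer(names(tab))
  structure(
    list(sizes = sizes, counts = as.integer(tab),
         total = sum(sizes * as.integer(tab)),
         num_classes = sum(as.integer(tab))),
    class = "freq_spectrum"
  )
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat("Frequency spectrum:", x$num_classes, "classes,", x$total, "records\n")
  df <- data.frame(class_size = x$sizes, n_classes = x$counts)
  print(df, row.names = FALSE)
  invisible(x)
}

# Number of classes of a given size (0 when absent from the spectrum).
spectrum_count <- function(sp, size) {
  i <- match(size, sp$sizes)
  if (is.na(i)) 0L else sp$counts[i]
}

#' Convert an equivalence-class table to record-level microdata
#'
#' Expands class counts into one record per population member with a single
#' synthetic quasi-identifier holding the class key.  Used to run the
#' record-level sampling harness on populations generated as class-size
#' multisets (for example by [generate_crp_population()]).
#'
#' @param x An `eq_classes` object.
#' @return A [microdata] object with one column `class`.
#' @export
as_microdata <- function(x) {
  stopifnot(inherits(x, "eq_classes"))
  microdata(data.frame(class = rep(x$keys, x$counts),
                       stringsAsFactors = FALSE), qi = "class")
}
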