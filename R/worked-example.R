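# Synthetic worked-example fixtures.  These construct small sample /
# population pairs with prescribed uniqueness structure: a 14-record
# disclosed data set with 9 sample uniques of which 2 are unique in a
# 40-record registry, and a 1000-record variant with exactly two records
# unique in both files.  They are generated in code, not shipped as data.

worked_example_tables <- function() {
  # sample: 9 singleton classes, one class of 3, one class of 2 (n = 14)
  # population: the same classes with counts
  #   1,1,2,2,2,2,2,2,2 (the nine sample-unique classes; two stay unique),
  #   4 and 3 (the repeated sample classes), plus 4 extra singleton
  #   classes and two filler classes (6, 7) absent from the sample,
  #   giving N = 40 with 6 population uniques (lambda3 = 0.15).
  cls <- data.frame(
    sex = c("M", "F", "M", "F", "M", "F", "M", "F", "M",
            "M", "F",
            "F", "M", "F", "M",
            "M", "F"),
    yob = c(1962, 1966, 1958, 1959, 1960, 1961, 1963, 1964, 1965,
            1970, 1971,
            1940, 1941, 1942, 1943,
            1980, 1981),
    pop_count = c(1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L,
                  4L, 3L,
                  1L, 1L, 1L, 1L,
                  6L, 7L),
    sample_count = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
                     3L, 2L,
                     0L, 0L, 0L, 0L,
                     0L, 0L)
  )
  expand <- function(count_col) {
    idx <- rep(seq_len(nrow(cls)), cls[[count_col]])
    microdata(data.frame(sex = cls$sex[idx],
                         yob = as.character(cls$yob[idx]),
                         stringsAsFactors = FALSE),
              qi = c("sex", "yob"))
  }
  list(population = expand("pop_count"), sample = expand("sample_count"))
}

worked_example_1000_tables <- function() {
  # sample: 2 singleton classes + 499 classes of size 2 (n = 1000); the
  # population adds one member to every doubleton so only the two
  # singletons are unique in either file.
  sex <- rep(c("M", "F"), length.out = 499L)
  key <- sprintf("k%03d", seq_len(499L))
  smp <- data.frame(
    sex = c("M", "F", rep(sex, each = 2L)),
    code = c("u1", "u2", rep(key, each = 2L)),
    stringsAsFactors = FALSE)
  pop <- data.frame(
    sex = c("M", "F", rep(sex, each = 3L)),
    code = c("u1", "u2", rep(key, each = 3L)),
    stringsAsFactors = FALSE)
  list(population = microdata(pop, qi = c("sex", "code")),
       sample = microdata(smp, qi = c("sex", "code")))
}

#' Worked-example risk metrics
#'
#' Builds the canonical small sample / registry pair — 14 disclosed
#' records, 9 of them sample-unique, exactly 2 of those unique in a
#' 40-record registry — and the 1000-record variant in which only two
#' records are unique in both files, then computes the exact risk metrics
#' for each.  Useful as a readable end-to-end demonstration of the
#' difference between conditional risk (lambda1), data-set risk (lambda2)
#' and population uniqueness (lambda3).
#'
#' @return A list with two [risk_metrics] objects: `small` (n = 14, where
#'   lambda1 = 2/9 and lambda2 = 2/14) and `large` (n = 1000, where
#'   lambda1 = 1 and lambda2 = 0.002).
#' @examples
#' worked_example()$small
#' @export
worked_example <- function() {
  small <- worked_example_tables()
  large <- worked_example_1000_tables()
  list(
    small = risk_metrics(build_equivalence_classes(small$population),
                         build_equivalence_classes(small$sample)),
    large = risk_metrics(build_equivalence_classes(large$population),
                         build_equivalence_classes(large$sample))
  )
}
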