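# Shared fixture builders.  Everything is generated in code at test time;
# no data files are read.

# Microdata from explicit value vectors.
md_from <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  microdata(df, qi = names(df))
}

# A population drawn from the slide-negative-binomial superpopulation law:
# K classes with sizes F = 1 + NegBin(r, p).
snb_population <- function(K, r, p, seed) {
  sizes <- with_test_seed(seed, 1L + stats::rnbinom(K, size = r, prob = p))
  eq_classes(sizes)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# Build a freq_spectrum directly from a size -> count map.
spectrum_from_map <- function(map) {
  sizes <- as.integer(names(map))
  spectrum_of(rep(sizes, unlist(map)))
}

# Count of adjacent increases in |x|, NA-skipping: the trend-violation
# counter used for the qualitative bias-vs-fraction property.
trend_violations <- function(x, eps = 1e-9) {
  v <- abs(x)
  v <- v[!is.na(v)]
  if (length(v) < 2L) return(0L)
  sum(diff(v) > eps)
}
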