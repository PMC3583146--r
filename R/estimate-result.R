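# Common result container for the uniqueness estimators.

new_estimate <- function(estimator, lambda3_hat, converged, params = NULL,
                         diagnostics = list()) {
  structure(
    list(estimator = estimator,
         lambda3_hat = lambda3_hat,
         converged = isTRUE(converged),
         params = params,
         diagnostics = diagnostics),
    class = "uniq_estimate"
  )
}

# Clamp an estimate into [0, 1], recording the event in diagnostics.
clamp_unit <- function(est) {
  if (is.na(est$lambda3_hat)) return(est)
  if (est$lambda3_hat < 0 || est$lambda3_hat > 1) {
    est$diagnostics$clamped <- TRUE
    est$diagnostics$raw_estimate <- est$lambda3_hat
    est$lambda3_hat <- min(1, max(0, est$lambda3_hat))
  } else {
    est$diagnostics$clamped <- FALSE
  }
  est
}

#' @export
print.uniq_estimate <- function(x, ...) {
  val <- if (is.na(x$lambda3_hat)) "NA" else sprintf("%.4f", x$lambda3_hat)
  cat(sprintf("%s estimate of population uniqueness: lambda3_hat = %s (%s)\n",
              x$estimator, val,
              if (x$converged) "converged" else "DID NOT CONVERGE"))
  if (length(x$params) > 0L) {
    cat("  parameters:",
        paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
              collapse = ", "), "\n")
  }
  invisible(x)
}
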