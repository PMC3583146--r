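# The E1 decision rule: select among Pitman, SNB and Zayatz according to
# the sampling fraction and a comparison of the SNB and Zayatz estimates.
# mu-argus is never consulted.

#' E1 decision rule for population-uniqueness estimation
#'
#' Combines three estimators by the rule:
#'
#' ```
#' If pi <= 0.1 then
#'   E1 = Pitman
#' Else
#'   If SNB converges then
#'     if Est(SNB) > Est(Zayatz) then E1 = Zayatz else E1 = SNB
#'   Else
#'     E1 = Zayatz
#' ```
#'
#' The boundary is inclusive (`pi = 0.1` routes to Pitman) and the SNB /
#' Zayatz comparison is strict, so a tie keeps SNB.  The returned estimate
#' is exactly the chosen component's result: if the chosen component itself
#' failed (for example Pitman non-convergence at small pi), its failed
#' result is returned with the trace — no further fallback is invented.
#'
#' @inheritParams estimate_pitman
#' @return A list with components `estimate` (the chosen component's
#'   `uniq_estimate`), `chosen` (estimator name) and `trace` (ordered list
#'   of branch predicates and the component estimates consulted).
#' @export
e1 <- function(sp, ctx) {
  check_spectrum_context(sp, ctx)
  if (ctx$pi <= 0.1) {
    components <- list(
      pitman = tryCatch(estimate_pitman(sp, ctx), error = function(e)
        new_estimate("pitman", NA_real_, FALSE,
                     diagnostics = list(error = conditionMessage(e)))))
  } else {
    components <- list(
      snb = tryCatch(estimate_snb(sp, ctx), error = function(e)
        new_estimate("snb", NA_real_, FALSE,
                     diagnostics = list(error = conditionMessage(e)))),
      zayatz = estimate_zayatz(sp, ctx))
  }
  e1_choose(ctx$pi, components)
}

# Pure branch logic of the E1 rule over already-computed component results;
# separated from e1() so every branch (including the tie) is directly
# testable.  `components` holds `pitman` when pi <= 0.1, else `snb` and
# `zayatz`.
e1_choose <- function(pi, components) {
  branch <- list(pi_le_0.1 = pi <= 0.1)
  if (branch$pi_le_0.1) {
    chosen <- "pitman"
    est <- components$pitman
  } else {
    snb <- components$snb; zay <- components$zayatz
    branch$snb_converged <- snb$converged
    if (snb$converged) {
      branch$snb_gt_zayatz <- snb$lambda3_hat > zay$lambda3_hat
      if (branch$snb_gt_zayatz) { chosen <- "zayatz"; est <- zay }
      else { chosen <- "snb"; est <- snb }
    } else {
      chosen <- "zayatz"; est <- zay
    }
  }
  consulted <- lapply(components, function(e) e$lambda3_hat)
  structure(
    list(estimate = est, chosen = chosen,
         trace = list(branch_path = branch, component_estimates = consulted)),
    class = "e1_result"
  )
}

#' @export
print.e1_result <- function(x, ...) {
  cat("E1 decision rule -> chose", x$chosen, "\n")
  for (nm in names(x$trace$branch_path)) {
    cat(sprintf("  %s: %s\n", nm, x$trace$branch_path[[nm]]))
  }
  print(x$estimate)
  invisible(x)
}
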