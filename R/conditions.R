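# Classed conditions so callers can distinguish validation failures from
# numerical ones. All abort helpers signal a condition inheriting from
# "degdom_error".

abort_degdom <- function(message, class, call = sys.call(-1), ...) {
  stop(errorCondition(message, ..., class = c(class, "degdom_error"),
                      call = call))
}

zero_cell_error <- function(cells) {
  abort_degdom(
    sprintf("zero cell(s) in collapsed 2x2 table (%s) under 'strict' continuity policy",
            paste(names(cells)[cells == 0], collapse = ", ")),
    class = "degdom_zero_cell_error", cells = cells)
}

degenerate_table_error <- function(row) {
  abort_degdom(
    sprintf("genotype row '%s' is entirely zero: 3-level genotype model not identifiable", row),
    class = "degdom_degenerate_table_error")
}

undefined_h_error <- function() {
  abort_degdom("h is undefined (0/0): both contrast log odds ratios are exactly zero",
               class = "degdom_undefined_h_error")
}

bound_violation_error <- function(D, lo, hi) {
  abort_degdom(
    sprintf("disequilibrium D = %.6g outside admissible bounds [%.6g, %.6g]", D, lo, hi),
    class = "degdom_bound_violation_error")
}

max_reject_error <- function(n_proposals, what) {
  abort_degdom(
    sprintf("rejection budget exhausted after %d proposals while drawing %s; the constraint window is infeasible or nearly so",
            n_proposals, what),
    class = "degdom_max_reject_error")
}

# Haldane continuity corrections are signalled as a classed warning so that
# simulation loops can muffle them without hiding unrelated warnings.
haldane_warning <- function(contrast) {
  warning(warningCondition(
    sprintf("zero cell in collapsed 2x2 table for the %s contrast; Haldane continuity correction (+0.5 per cell) applied",
            contrast),
    class = c("degdom_haldane_warning", "degdom_warning")))
}

#' Evaluate an expression with Haldane-correction warnings muffled
#'
#' Continuity corrections are routine in simulations with rare genotypes;
#' this wrapper silences only the classed correction warning and lets every
#' other condition through.
#'
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
quiet_haldane <- function(expr) {
  withCallingHandlers(expr, degdom_haldane_warning = function(w) {
    invokeRestart("muffleWarning")
  })
}
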