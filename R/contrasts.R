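# Genetic contrasts on the 3x2 genotype table.
#
# Each contrast collapses the table to a 2x2 comparison; the log odds ratio
# carries the Woolf asymptotic variance (sum of reciprocal cells). Only the
# additive and co-dominant contrasts are orthogonal (coefficient vectors
# (1,0,-1) and (-0.5,1,-0.5), dot product 0) and only those two feed the
# inferential machinery; the dominant and recessive contrasts are kept as
# descriptive extras for reports.

.contrast_defs <- list(
  additive = list(
    coefficients = c(1, 0, -1),
    # mtmt vs wtwt, heterozygotes ignored: a/b = case mtmt/wtwt, c/d = control
    collapse = function(n) c(a = n[3L, 2L], b = n[1L, 2L],
                             c = n[3L, 1L], d = n[1L, 1L])
  ),
  `co-dominant` = list(
    coefficients = c(-0.5, 1, -0.5),
    # wtmt vs pooled homozygotes
    collapse = function(n) c(a = n[2L, 2L], b = n[1L, 2L] + n[3L, 2L],
                             c = n[2L, 1L], d = n[1L, 1L] + n[3L, 1L])
  ),
  dominant = list(
    coefficients = c(-1, 0.5, 0.5),
    collapse = function(n) c(a = n[2L, 2L] + n[3L, 2L], b = n[1L, 2L],
                             c = n[2L, 1L] + n[3L, 1L], d = n[1L, 1L])
  ),
  recessive = list(
    coefficients = c(-0.5, -0.5, 1),
    collapse = function(n) c(a = n[3L, 2L], b = n[1L, 2L] + n[2L, 2L],
                             c = n[3L, 1L], d = n[1L, 1L] + n[2L, 1L])
  )
)

#' Estimate a genetic contrast odds ratio from a genotype table
#'
#' Collapses the 3x2 table to the 2x2 comparison defined by the contrast,
#' then returns the log odds ratio ln(ad/bc), its Woolf variance
#' 1/a + 1/b + 1/c + 1/d, the z statistic and two-sided normal p-value.
#' With the sign convention used throughout, a positive additive log odds
#' ratio means the mutant homozygote has higher disease odds than the
#' wild-type homozygote, and a positive co-dominant log odds ratio means
#' the heterozygote has higher odds than the pooled homozygotes.
#'
#' @param table A [genotype_table()].
#' @param contrast One of `"additive"`, `"co-dominant"`, `"dominant"`,
#'   `"recessive"`.
#' @param correction Continuity policy when a collapsed cell is zero:
#'   `"haldane"` (default) adds 0.5 to all four collapsed cells and signals
#'   a classed warning; `"strict"` raises a zero-cell error.
#' @return A `contrast_estimate`: list with `name`, `coefficients`,
#'   `log_or`, `variance`, `z`, `p_two_sided`, `correction_applied` and the
#'   collapsed `cells`.
#' @examples
#' additive_log_or(example_tables()$adh2)   # ln(theta_a) = 2.08
#' @export
genotype_contrast <- function(table,
                              contrast = c("additive", "co-dominant",
                                           "dominant", "recessive"),
                              correction = c("haldane", "strict")) {
  assert_genotype_table(table)
  contrast <- match.arg(contrast)
  correction <- match.arg(correction)
  def <- .contrast_defs[[contrast]]
  cells <- def$collapse(table$counts)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (correction == "strict") zero_cell_error(cells)
    haldane_warning(contrast)
    cells <- cells + 0.5
    corrected <- TRUE
  }
  log_or <- log(cells[["a"]] * cells[["d"]]) - log(cells[["b"]] * cells[["c"]])
  variance <- sum(1 / cells)
  z <- log_or / sqrt(variance)
  structure(list(name = contrast,
                 coefficients = def$coefficients,
                 log_or = log_or,
                 variance = variance,
                 z = z,
                 p_two_sided = 2 * stats::pnorm(-abs(z)),
                 correction_applied = corrected,
                 cells = cells),
            class = "contrast_estimate")
}

#' @rdname genotype_contrast
#' @export
additive_log_or <- function(table, correction = c("haldane", "strict")) {
  genotype_contrast(table, "additive", correction)
}

#' @rdname genotype_contrast
#' @export
codominant_log_or <- function(table, correction = c("haldane", "strict")) {
  genotype_contrast(table, "co-dominant", correction)
}

#' @export
print.contrast_estimate <- function(x, ...) {
  cat(sprintf("%s contrast: ln(OR) = %.2f (var %.4f), z = %.2f, p = %.2g%s\n",
              x$name, x$log_or, x$variance, x$z, x$p_two_sided,
              if (x$correction_applied) " [Haldane-corrected]" else ""))
  invisible(x)
}
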