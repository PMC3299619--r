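# Degree of dominance h = ln(theta_co) / |ln(theta_a)| and the hypothesis
# ladder that turns it into a mode-of-inheritance call:
#   h = 0          non-dominance (heterozygote risk midway)
#   -1 <= h < 0    dominance of the wild-type allele
#   0 < h <= 1     dominance of the mutant allele
#   h > 1          over-dominance  (heterozygote riskier than mtmt)
#   h < -1         under-dominance (heterozygote safer than wtwt)

#' Half-normal variance factor
#'
#' The factor `1 - 2/pi` by which the variance of `|ln(theta_a)|` relates to
#' the variance of `ln(theta_a)` when the log odds ratio is treated as
#' normal: taking the absolute value folds the distribution, and the folded
#' (half-normal) variance is `sigma^2 (1 - 2/pi)`.
#' @return `1 - 2/pi` (about 0.36338).
#' @export
half_normal_factor <- function() 1 - 2 / pi

#' Degree-of-dominance index
#'
#' `h = ln(theta_co) / |ln(theta_a)|`. The sign of the co-dominant log odds
#' ratio sets the direction of dominance; its magnitude relative to the
#' additive log odds ratio sets the degree. `h` ranges over the whole real
#' line: values beyond +/-1 indicate over-/under-dominance.
#'
#' @param co Co-dominant `contrast_estimate` (from [codominant_log_or()]).
#' @param add Additive `contrast_estimate` from the same table.
#' @return A scalar; `+Inf`/`-Inf` (carrying the sign of the co-dominant
#'   log odds ratio) when the additive log odds ratio is exactly zero.
#' @examples
#' tab <- example_tables()$adh2
#' h_index(codominant_log_or(tab), additive_log_or(tab))   # 0.23
#' @export
h_index <- function(co, add) {
  stopifnot(inherits(co, "contrast_estimate"), inherits(add, "contrast_estimate"))
  if (add$log_or == 0) {
    if (co$log_or == 0) undefined_h_error()
    return(sign(co$log_or) * Inf)
  }
  co$log_or / abs(add$log_or)
}

#' One-sided test for over- or under-dominance
#'
#' Tests H0: |h| = 1 against |h| > 1 on the log-odds scale via the statistic
#' `k`: when `ln(theta_a) > 0`, `k = ln(theta_co) - ln(theta_a)`; when
#' `ln(theta_a) < 0`, `k = ln(theta_co) + ln(theta_a)`. Its variance is
#' `Var[ln(theta_co)] + Var[ln(theta_a)] * (1 - 2/pi)`, the half-normal
#' factor accounting for the absolute value taken of the additive term.
#' The p-value is one-sided in the tested direction: upper tail for
#' over-dominance (k > 0), lower tail for under-dominance (k < 0).
#'
#' @param co,add `contrast_estimate`s from the same table.
#' @param direction `"over"` or `"under"`.
#' @return List with `k`, `var_k`, `z` and `p_one_sided`.
#' @export
k_test <- function(co, add, direction = c("over", "under")) {
  stopifnot(inherits(co, "contrast_estimate"), inherits(add, "contrast_estimate"))
  direction <- match.arg(direction)
  k <- if (add$log_or >= 0) co$log_or - add$log_or else co$log_or + add$log_or
  var_k <- co$variance + add$variance * half_normal_factor()
  z <- k / sqrt(var_k)
  p <- if (direction == "over") stats::pnorm(z, lower.tail = FALSE)
       else stats::pnorm(z)
  list(k = k, var_k = var_k, z = z, p_one_sided = p)
}

#' Classify the mode of inheritance of a genotype table
#'
#' Runs the ordered hypothesis ladder. (1) If the co-dominant contrast is
#' non-significant at `alpha` the call is `non-dominance`: the heterozygote
#' risk is consistent with the midpoint of the two homozygotes. (2) If
#' significant and `-1 <= h < 0` the wild-type allele is dominant
#' (`dominance-of-wt`); `0 < h <= 1` gives `dominance-of-mt`. (3) If
#' `|h| > 1` the one-sided [k_test()] is run in the matching direction:
#' significant gives `over-dominance`/`under-dominance`, otherwise
#' `dominance-unresolved` (dominance is established but its excess beyond
#' the additive span is not beyond chance).
#'
#' Significance gating uses the z-test of the co-dominant contrast; the
#' deviance p-value of `D_Lco` is reported alongside and the two agree
#' closely on well-conditioned tables. `h` is always computed and reported,
#' including under non-dominance, so batch summaries can plot it.
#'
#' @param table A [genotype_table()].
#' @param alpha Significance level for every gate (default 0.05). No
#'   multiplicity correction is applied here; genome-wide users should
#'   divide `alpha` themselves (the CLI exposes a Bonferroni divisor).
#' @param correction Continuity policy passed to the contrasts.
#' @return A `dominance_call`: list with `h`, `mode`, `codominant_p`
#'   (z-test), `codominant_deviance_p`, `k`, `var_k`, `z_k`,
#'   `p_k_one_sided` (NA unless the ladder reached the k-test), `alpha`,
#'   `half_normal_factor`, and the two `contrast_estimate`s.
#' @examples
#' classify_dominance(example_tables()$bdnf)   # under-dominance, h = -1.82
#' @export
classify_dominance <- function(table, alpha = 0.05,
                               correction = c("haldane", "strict")) {
  assert_genotype_table(table)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  correction <- match.arg(correction)
  co <- genotype_contrast(table, "co-dominant", correction)
  add <- genotype_contrast(table, "additive", correction)
  dev <- fit_genotype_deviance(table)
  h <- if (co$log_or == 0 && add$log_or == 0) 0 else h_index(co, add)

  k <- var_k <- z_k <- p_k <- NA_real_
  if (co$p_two_sided >= alpha) {
    mode <- "non-dominance"
  } else if (abs(h) <= 1) {
    mode <- if (h < 0) "dominance-of-wt" else "dominance-of-mt"
  } else {
    direction <- if (h > 1) "over" else "under"
    kt <- k_test(co, add, direction)
    k <- kt$k; var_k <- kt$var_k; z_k <- kt$z; p_k <- kt$p_one_sided
    mode <- if (p_k < alpha) paste0(direction, "-dominance")
            else "dominance-unresolved"
  }
  structure(list(h = h, mode = mode,
                 codominant_p = co$p_two_sided,
                 codominant_deviance_p = dev$p_lco,
                 k = k, var_k = var_k, z_k = z_k, p_k_one_sided = p_k,
                 alpha = alpha,
                 half_normal_factor = half_normal_factor(),
                 codominant = co, additive = add,
                 deviance = dev),
            class = "dominance_call")
}

#' @export
print.dominance_call <- function(x, ...) {
  cat(sprintf("mode of inheritance: %s\n", x$mode))
  cat(sprintf("  h = %.2f  (ln OR co-dominant %.2f / |ln OR additive %.2f|)\n",
              x$h, x$codominant$log_or, x$additive$log_or))
  cat(sprintf("  co-dominant z-test p = %.3g (deviance p = %.3g), alpha = %g\n",
              x$codominant_p, x$codominant_deviance_p, x$alpha))
  if (!is.na(x$k))
    cat(sprintf("  k = %.3f, Var(k) = %.4f, z = %.2f, one-sided p = %.3g\n",
                x$k, x$var_k, x$z_k, x$p_k_one_sided))
  invisible(x)
}
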