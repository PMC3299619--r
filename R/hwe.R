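# Hardy-Weinberg disequilibrium in the controls and its effect on h.
#
# Control genotype frequencies are modelled (after Weir) as
#   f(wtwt) = p^2 + D,  f(wtmt) = 2pq - 2D,  f(mtmt) = q^2 + D,
# with p the wild-type allele frequency and D the disequilibrium
# coefficient, bounded by max(-p^2, -q^2) <= D <= pq. D > 0 is a homozygote
# excess (e.g. population stratification via the Wahlund effect), D < 0 a
# heterozygote excess.

#' Estimate Hardy-Weinberg disequilibrium in the controls
#'
#' Allele frequencies by gene counting on the control column, the
#' disequilibrium coefficient `D = n11/n - p^2`, its admissible bounds, and
#' a test of H0: D = 0 (Pearson chi-squared with 1 df by default; the exact
#' conditional test is available via `method = "exact"`).
#'
#' @param table A [genotype_table()].
#' @param method `"chisq"` (default, no continuity correction) or
#'   `"exact"` (conditional test on the heterozygote count given the
#'   minor-allele count).
#' @return An `hwe_state`: list with `p` (wt frequency), `q`, `n_controls`,
#'   `D`, `D_min`, `D_max`, `chi2`, `p_hwe` and `method`.
#' @examples
#' estimate_disequilibrium(example_tables()$ace)
#' @export
estimate_disequilibrium <- function(table, method = c("chisq", "exact")) {
  assert_genotype_table(table)
  method <- match.arg(method)
  n <- table$counts[, "controls"]
  tot <- sum(n)
  p <- unname((2 * n[1L] + n[2L]) / (2 * tot))
  q <- 1 - p
  D <- n[1L] / tot - p^2
  e <- tot * c(p^2, 2 * p * q, q^2)
  chi2 <- sum(ifelse(e > 0, (n - e)^2 / e, 0))
  p_hwe <- if (method == "chisq") {
    if (p %in% c(0, 1)) 1 else stats::pchisq(chi2, 1L, lower.tail = FALSE)
  } else {
    hwe_exact_p(n)
  }
  structure(list(p = unname(p), q = unname(q), n_controls = tot,
                 D = unname(D),
                 D_min = max(-p^2, -q^2), D_max = p * q,
                 chi2 = unname(chi2), p_hwe = unname(p_hwe),
                 method = method),
            class = "hwe_state")
}

#' @export
print.hwe_state <- function(x, ...) {
  cat(sprintf("HWE in controls (n = %d): p(wt) = %.4f, D = %.5f (bounds [%.5f, %.5f])\n",
              x$n_controls, x$p, x$D, x$D_min, x$D_max))
  cat(sprintf("  %s test: chi2 = %.3f, p = %.3g\n",
              if (x$method == "chisq") "chi-squared (1 df)" else "exact",
              x$chi2, x$p_hwe))
  invisible(x)
}

# Exact HWE test: conditional distribution of the heterozygote count given
# the minor-allele count (sum over genotype configurations with probability
# <= that observed). Log-scale recurrence keeps it stable at n = 1e4.
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  n_minor <- min(2 * counts[1L] + counts[2L], 2 * counts[3L] + counts[2L])
  het_obs <- counts[2L]
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  logp <- vapply(hets, function(h) {
    homr <- (n_minor - h) / 2
    homc <- n - h - homr
    lgamma(n + 1) - lgamma(h + 1) - lgamma(homr + 1) - lgamma(homc + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1L))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[match(het_obs, hets)] * (1 + 1e-12)])
}

#' Weir-model control frequencies
#'
#' @param p Wild-type allele frequency in controls.
#' @param D Disequilibrium coefficient.
#' @return Numeric vector `(p^2 + D, 2pq - 2D, q^2 + D)`.
#' @keywords internal
weir_frequencies <- function(p, D) {
  q <- 1 - p
  c(p^2 + D, 2 * p * q - 2 * D, q^2 + D)
}

#' Contrast odds ratios under parametric Weir-model controls
#'
#' Replaces the control column by the parametric Weir frequencies and
#' returns the two contrast odds ratios:
#' `theta_a = (n32/n12) (p^2 + D)/(q^2 + D)` and
#' `theta_co = (n22/(n12 + n32)) (p^2 + q^2 + 2D)/(2pq - 2D)`.
#' At `D = 0` these coincide with the plain table odds ratios computed from
#' HWE-proportion controls; at `D = pq` the additive odds ratio attains its
#' lower bound `(n32/n12)(p/q)` and the co-dominant one diverges; at
#' `D = -q^2` the additive one diverges.
#'
#' @param case_counts Case column `(n12, n22, n32)` (wtwt, wtmt, mtmt);
#'   non-negative, `n12 > 0` and `n12 + n32 > 0` required.
#' @param p Wild-type allele frequency in controls; `q = 1 - p`.
#' @param D Disequilibrium coefficient, inside the admissible bounds.
#' @param n_controls Control column total for the induced parametric table
#'   (only used in the returned `control_counts`; the odds ratios do not
#'   depend on it).
#' @return List with `theta_a`, `theta_co`, `h` (from the log odds ratios),
#'   `control_freqs` and `control_counts`.
#' @export
biased_contrasts <- function(case_counts, p, D, n_controls = 400L) {
  stopifnot(length(case_counts) == 3L, all(case_counts >= 0),
            p > 0, p < 1)
  q <- 1 - p
  lo <- max(-p^2, -q^2); hi <- p * q
  if (D < lo - 1e-12 || D > hi + 1e-12) bound_violation_error(D, lo, hi)
  f <- weir_frequencies(p, D)
  n12 <- case_counts[1L]; n22 <- case_counts[2L]; n32 <- case_counts[3L]
  if (n12 <= 0 || n12 + n32 <= 0)
    abort_degdom("case counts give a zero denominator for the parametric odds ratios",
                 class = "degdom_value_error")
  # endpoint divergences: at D = -q^2 the additive denominator vanishes, at
  # D = pq the co-dominant one does; report +Inf rather than fp noise
  eps <- 1e-12
  theta_a <- if (q^2 + D <= eps) Inf
             else (n32 / n12) * (p^2 + D) / (q^2 + D)
  theta_co <- if (2 * p * q - 2 * D <= eps) Inf
              else (n22 / (n12 + n32)) * (p^2 + q^2 + 2 * D) / (2 * p * q - 2 * D)
  h <- if (theta_a == 1) sign(log(theta_co)) * Inf
       else log(theta_co) / abs(log(theta_a))
  list(theta_a = theta_a, theta_co = theta_co, h = h,
       control_freqs = f, control_counts = n_controls * f)
}

#' Simulate the bias in h induced by Hardy-Weinberg disequilibrium
#'
#' Monte-Carlo reproduction of the disequilibrium bias experiment: case
#' genotype counts are drawn uniformly on the integer 3-composition of
#' `n_cases` with the mutant-allele frequency restricted to
#' `maf_window`; controls are parametric Weir-model frequencies with
#' `q_controls <= q_cases` and `|D| >= d_abs_min` in the requested arm.
#' Each replicate records the biased `h` (at the drawn D) and the reference
#' `h` at D = 0 with the same allele frequencies, so the bias is isolated
#' from sampling noise in the controls.
#'
#' @param n_replicates Number of replicates (default 10000).
#' @param d_sign `"positive"` (homozygote excess) or `"negative"`
#'   (heterozygote excess).
#' @param n_cases,n_controls Sample sizes (default 400/400).
#' @param maf_window Case mutant-allele frequency window, default
#'   `c(0.05, 0.40)`.
#' @param d_abs_min Minimum |D| (default 0.005).
#' @param seed Mandatory integer seed.
#' @return Data frame with columns `seed`, `replicate`, `D`, `maf`
#'   (case maf), `h_biased`, `h_ref`, `sign_flip`.
#' @export
simulate_hwe_bias <- function(n_replicates = 10000L,
                              d_sign = c("positive", "negative"),
                              n_cases = 400L, n_controls = 400L,
                              maf_window = c(0.05, 0.40),
                              d_abs_min = 0.005,
                              seed) {
  d_sign <- match.arg(d_sign)
  if (missing(seed) || !is.numeric(seed))
    abort_degdom("an integer 'seed' is mandatory for simulation reproducibility",
                 class = "degdom_config_error")
  stopifnot(n_replicates >= 1, n_cases >= 1, length(maf_window) == 2L,
            maf_window[1L] >= 0, maf_window[2L] <= 1,
            maf_window[1L] < maf_window[2L], d_abs_min > 0)
  set.seed(as.integer(seed))
  # smallest q_controls for which |D| >= d_abs_min is attainable:
  # positive arm needs pq > d_abs_min, negative arm needs q^2 > d_abs_min
  q_floor <- if (d_sign == "positive") {
    (1 - sqrt(1 - 4 * d_abs_min)) / 2 + 1e-9
  } else {
    sqrt(d_abs_min) + 1e-9
  }
  if (maf_window[2L] <= q_floor)
    abort_degdom("maf window too low for the requested |D| arm: no admissible q_controls exists",
                 class = "degdom_config_error")
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    repeat {
      block <- draw_simplex_counts(16L, n_cases, maf_window)
      if (ncol(block) == 0L) next
      cc <- block[, 1L]
      q_cases <- (cc[2L] + 2 * cc[3L]) / (2 * n_cases)
      # all-positive case cells keep both parametric odds ratios finite;
      # q_cases must leave room for an admissible q_controls <= q_cases
      if (all(cc > 0) && q_cases > q_floor) break
    }
    repeat {
      q_ctrl <- stats::runif(1L, q_floor, q_cases)
      p <- 1 - q_ctrl
      hi <- p * q_ctrl; lo <- max(-p^2, -q_ctrl^2)
      if (d_sign == "positive") {
        if (hi > d_abs_min) { D <- stats::runif(1L, d_abs_min, hi); break }
      } else {
        if (-lo > d_abs_min) { D <- stats::runif(1L, lo, -d_abs_min); break }
      }
    }
    b <- biased_contrasts(cc, p, D, n_controls)
    ref <- biased_contrasts(cc, p, 0, n_controls)
    out[[r]] <- data.frame(seed = as.integer(seed), replicate = r,
                           D = D, maf = q_cases,
                           h_biased = b$h, h_ref = ref$h,
                           sign_flip = sign(b$h) != sign(ref$h))
  }
  do.call(rbind, out)
}

#' Write a simulation record table as TSV
#'
#' Plain tab-separated output with a header; used by every simulator in the
#' package so downstream plotting has one format to read.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
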