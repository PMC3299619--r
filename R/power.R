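# Monte-Carlo power of the co-dominant contrast under HWE-conforming
# controls. Genotype counts are "randomly generated" as uniform draws on
# the integer 3-composition of n (Dirichlet(1,1,1) scaled and rounded with
# largest-remainder correction); cases are accepted when their mutant
# allele frequency falls in the target window, controls when they pass the
# HWE test (p >= 0.05) and satisfy q_controls <= q_cases.

# Uniform simplex draws rounded to integer compositions of n; optional maf
# window filter. Returns a 3 x k matrix (possibly 0 columns).
draw_simplex_counts <- function(k, n, maf_window = NULL) {
  w <- matrix(stats::rexp(3L * k), nrow = 3L)
  w <- sweep(w, 2L, colSums(w), "/")
  x <- w * n
  base <- floor(x)
  short <- n - colSums(base)
  rem <- x - base
  for (j in which(short > 0L)) {
    top <- order(rem[, j], decreasing = TRUE)[seq_len(short[j])]
    base[top, j] <- base[top, j] + 1L
  }
  if (!is.null(maf_window)) {
    q <- (base[2L, ] + 2 * base[3L, ]) / (2 * n)
    base <- base[, q >= maf_window[1L] & q <= maf_window[2L], drop = FALSE]
  }
  base
}

# Vectorised HWE chi-squared p for columns of a 3 x k control-count matrix.
hwe_p_columns <- function(m) {
  n <- colSums(m)
  p <- (2 * m[1L, ] + m[2L, ]) / (2 * n)
  q <- 1 - p
  D <- m[1L, ] / n - p^2
  denom <- p^2 * q^2
  chi2 <- ifelse(denom > 0, n * D^2 / denom, 0)
  stats::pchisq(chi2, 1L, lower.tail = FALSE)
}

#' Draw one case-control table under the power-simulation constraints
#'
#' Rejection sampling: case counts uniform on the integer 3-composition of
#' `n_cases`, accepted when the case maf lies in `maf_window`; control
#' counts likewise on `n_controls`, accepted when the HWE chi-squared test
#' gives p >= `hwe_p_threshold` and `q_controls <= q_cases`.
#'
#' @param n_cases,n_controls Column totals (default 400/400).
#' @param maf_window Length-2 case maf window.
#' @param hwe_p_threshold HWE acceptance threshold for controls
#'   (default 0.05).
#' @param max_reject Rejection budget (proposals per column) before
#'   signalling an infeasible window (default 1e5).
#' @return A [genotype_table()]; the acceptance bookkeeping is attached as
#'   attribute `proposals` (named vector, cases/controls).
#' @export
generate_case_control_pair <- function(n_cases = 400L, n_controls = 400L,
                                       maf_window = c(0.09, 0.11),
                                       hwe_p_threshold = 0.05,
                                       max_reject = 1e5) {
  stopifnot(length(maf_window) == 2L, maf_window[1L] <= maf_window[2L])
  block <- 512L
  used_cases <- 0L
  cases <- NULL
  while (is.null(cases)) {
    if (used_cases >= max_reject) max_reject_error(used_cases, "case counts")
    m <- draw_simplex_counts(block, n_cases, maf_window)
    used_cases <- used_cases + block
    if (ncol(m) > 0L) cases <- m[, 1L]
  }
  q_cases <- (cases[2L] + 2 * cases[3L]) / (2 * n_cases)
  used_ctrl <- 0L
  controls <- NULL
  while (is.null(controls)) {
    if (used_ctrl >= max_reject) max_reject_error(used_ctrl, "control counts")
    m <- draw_simplex_counts(block, n_controls)
    used_ctrl <- used_ctrl + block
    q <- (m[2L, ] + 2 * m[3L, ]) / (2 * n_controls)
    ok <- q <= q_cases & hwe_p_columns(m) >= hwe_p_threshold
    if (any(ok)) controls <- m[, which(ok)[1L]]
  }
  tab <- genotype_table(controls, cases)
  attr(tab, "proposals") <- c(cases = used_cases, controls = used_ctrl)
  tab
}

#' Monte-Carlo power of the co-dominant contrast
#'
#' For each case-maf window, `replicates` tables are drawn under the
#' constraints of [generate_case_control_pair()]; each replicate's
#' co-dominant z-test p-value and realized h-index are computed, and power
#' is the proportion of p < `alpha` within bins of realized h (width 0.1
#' over `[-1, -0.1]` and `[0.1, 1]` by default; replicates outside the
#' bins are dropped from the table but counted in the acceptance log).
#' Binning is on realized h because the generator cannot target h directly.
#'
#' @param maf_windows List of length-2 case-maf windows; defaults to the
#'   three standard windows `[0.09, 0.11]`, `[0.09, 0.21]`, `[0.39, 0.41]`.
#' @param replicates Replicates per window (default 10000).
#' @param alpha Significance level (default 0.05).
#' @param n_cases,n_controls Sample sizes (default 400/400).
#' @param h_bin_edges Bin edges for realized h; default
#'   `seq(-1, 1, by = 0.1)` with the interval `(-0.1, 0.1)` excluded.
#' @param hwe_p_threshold HWE acceptance threshold (default 0.05).
#' @param seed Mandatory integer seed.
#' @return Data frame with `maf_lo`, `maf_hi`, `h_bin_lo`, `h_bin_hi`,
#'   `power`, `se` (binomial), `n_reps`; acceptance bookkeeping in
#'   attribute `acceptance` (data frame per window: replicates, proposals,
#'   generator note).
#' @export
estimate_power <- function(maf_windows = list(c(0.09, 0.11),
                                              c(0.09, 0.21),
                                              c(0.39, 0.41)),
                           replicates = 10000L,
                           alpha = 0.05,
                           n_cases = 400L, n_controls = 400L,
                           h_bin_edges = seq(-1, 1, by = 0.1),
                           hwe_p_threshold = 0.05,
                           seed) {
  if (missing(seed) || !is.numeric(seed))
    abort_degdom("an integer 'seed' is mandatory for simulation reproducibility",
                 class = "degdom_config_error")
  set.seed(as.integer(seed))
  out <- list(); acc <- list()
  for (w in maf_windows) {
    hs <- ps <- numeric(replicates)
    props <- 0
    for (r in seq_len(replicates)) {
      tab <- generate_case_control_pair(n_cases, n_controls, w,
                                        hwe_p_threshold)
      props <- props + sum(attr(tab, "proposals"))
      co <- quiet_haldane(codominant_log_or(tab))
      ad <- quiet_haldane(additive_log_or(tab))
      ps[r] <- co$p_two_sided
      hs[r] <- if (ad$log_or == 0) sign(co$log_or) * Inf
               else co$log_or / abs(ad$log_or)
    }
    bin <- cut(hs, h_bin_edges, right = TRUE, include.lowest = FALSE)
    # drop the (-0.1, 0.1] near-null sliver from the reported bins: the
    # parameter space of interest is 0.1 <= |h| <= 1
    keep <- !is.na(bin) & !(hs > -0.1 & hs <= 0.1)
    for (lev in levels(bin)) {
      idx <- keep & bin == lev
      nb <- sum(idx)
      if (nb == 0L) next
      pw <- mean(ps[idx] < alpha)
      lo <- as.numeric(sub("^\\((.*),.*", "\\1", lev))
      out[[length(out) + 1L]] <- data.frame(
        maf_lo = w[1L], maf_hi = w[2L],
        h_bin_lo = lo, h_bin_hi = lo + diff(h_bin_edges)[1L],
        power = pw, se = sqrt(pw * (1 - pw) / nb), n_reps = nb)
    }
    acc[[length(acc) + 1L]] <- data.frame(
      maf_lo = w[1L], maf_hi = w[2L], replicates = replicates,
      proposals = props,
      generator = "uniform integer 3-composition (Dirichlet(1,1,1), largest-remainder rounding)")
  }
  res <- do.call(rbind, out)
  attr(res, "acceptance") <- do.call(rbind, acc)
  res
}

#' Co-dominant rejection rate under an exactly additive generator
#'
#' Type-I calibration for the non-dominance gate. Controls follow HWE at
#' mutant frequency `q`; cases are control frequencies enriched by
#' genotype odds `(1, o2, theta_a)` with the heterozygote odds `o2` set to
#' the control-frequency-weighted mean of the homozygote odds, which makes
#' the population co-dominant odds ratio exactly 1 (the null of the gate)
#' while the additive association `theta_a` is free. Both columns are then
#' multinomial samples and the co-dominant z-test is applied to each.
#'
#' @param replicates Number of simulated tables (default 10000).
#' @param q Control mutant allele frequency (default 0.3).
#' @param theta_a Population additive odds ratio (default 2).
#' @param n_cases,n_controls Sample sizes (default 400/400).
#' @param alpha Significance level (default 0.05).
#' @param seed Mandatory integer seed.
#' @return List with `rejection_rate`, `se`, `replicates` and the
#'   generating `case_freqs`/`control_freqs`.
#' @export
simulate_additive_null <- function(replicates = 10000L, q = 0.3,
                                   theta_a = 2,
                                   n_cases = 400L, n_controls = 400L,
                                   alpha = 0.05, seed) {
  if (missing(seed) || !is.numeric(seed))
    abort_degdom("an integer 'seed' is mandatory for simulation reproducibility",
                 class = "degdom_config_error")
  stopifnot(q > 0, q < 1, theta_a > 0)
  set.seed(as.integer(seed))
  p <- 1 - q
  f_ctl <- c(p^2, 2 * p * q, q^2)
  o2 <- (f_ctl[1L] * 1 + f_ctl[3L] * theta_a) / (f_ctl[1L] + f_ctl[3L])
  odds <- c(1, o2, theta_a)
  f_case <- f_ctl * odds / sum(f_ctl * odds)
  ctl <- stats::rmultinom(replicates, n_controls, f_ctl)
  cas <- stats::rmultinom(replicates, n_cases, f_case)
  rej <- logical(replicates)
  for (r in seq_len(replicates)) {
    tab <- genotype_table(ctl[, r], cas[, r])
    co <- quiet_haldane(codominant_log_or(tab))
    rej[r] <- co$p_two_sided < alpha
  }
  rate <- mean(rej)
  list(rejection_rate = rate,
       se = sqrt(rate * (1 - rate) / replicates),
       replicates = replicates,
       control_freqs = f_ctl, case_freqs = f_case)
}
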