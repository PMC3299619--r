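# One-locus, two-allele selection cohort model with known true dominance H.
#
# A cohort starts at time t1 in Hardy-Weinberg proportions (p1^2, 2 p1 q1,
# q1^2) for alleles wt/mt. Over the interval t1 -> t2 relative survival is
# genotype-dependent with fitnesses (1, 1 - H s, 1 - s): the mutant
# homozygote loses a fraction s, and H in [0, 1] is the true degree of
# dominance of mt (0 recessive, 0.5 co-dominant, 1 dominant). The "disease"
# is death in the interval, so controls are the initial cohort and cases
# are the individuals that died. A genotype-independent background
# mortality m keeps every genotype represented among the cases.

#' Define a selection-cohort scenario
#'
#' @param q1 Initial mutant allele frequency, in `[0.05, 0.5]`.
#' @param s Selection coefficient against the mutant homozygote, in
#'   `[0, 1)` (`s = 0` is the neutral control scenario).
#' @param H True degree of dominance of the mutant allele, in `[0, 1]`.
#' @param N Cohort size at t1 (default 10000). Only the parametric
#'   frequencies enter the sampling; `N` documents the intended cohort.
#' @param mortality Genotype-independent background death probability
#'   (default 0.05), which guarantees non-zero case frequencies for every
#'   genotype.
#' @param n_cases,n_controls Case-control sample sizes (default 400/400).
#' @param seed Optional integer seed used by [sample_table()].
#' @param hazard Composition of background and selective mortality:
#'   `"competing"` (default), death probability `1 - (1 - m) w_g`, reduces
#'   to pure selection at `m = 0` and to uniform `m` at `s = 0`;
#'   `"additive"`, `m + (1 - w_g)`, kept for sensitivity checks.
#' @return A `cohort_scenario` list.
#' @export
cohort_scenario <- function(q1, s, H, N = 10000L, mortality = 0.05,
                            n_cases = 400L, n_controls = 400L,
                            seed = NULL,
                            hazard = c("competing", "additive")) {
  hazard <- match.arg(hazard)
  check <- function(ok, msg) if (!ok) abort_degdom(msg, class = "degdom_config_error")
  check(is.numeric(q1) && q1 >= 0.05 && q1 <= 0.5,
        "'q1' must lie in [0.05, 0.5]")
  check(is.numeric(s) && s >= 0 && s < 1, "'s' must lie in [0, 1)")
  check(is.numeric(H) && H >= 0 && H <= 1, "'H' must lie in [0, 1]")
  check(is.numeric(mortality) && mortality >= 0 && mortality < 1,
        "'mortality' must lie in [0, 1)")
  check(mortality > 0 || s > 0,
        "with mortality = 0 and s = 0 nobody dies: no cases exist")
  check(N >= 1 && n_cases >= 1 && n_controls >= 1,
        "'N', 'n_cases' and 'n_controls' must be positive")
  structure(list(q1 = q1, s = s, H = H, N = as.integer(N),
                 mortality = mortality,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 seed = seed, hazard = hazard),
            class = "cohort_scenario")
}

#' Parametric control and case genotype frequencies of a cohort scenario
#'
#' Controls are the initial cohort, i.e. the t1 Hardy-Weinberg proportions.
#' Case frequencies are proportional to the expected deaths per genotype:
#' the t1 frequency times the per-genotype death probability (see
#' [cohort_scenario()]'s `hazard`). Survivor frequencies (the t2 column of
#' the selection model, `(p1^2, 2 p1 q1 (1 - Hs), q1^2 (1 - s)) / wbar`)
#' are returned as a cross-check; background mortality cancels out of them
#' under the competing-risks composition.
#'
#' @param scenario A [cohort_scenario()].
#' @return List with `control_freqs`, `case_freqs`, `survivor_freqs`,
#'   `fitness`, `death_prob` and mean fitness `wbar` (all genotype vectors
#'   ordered wtwt, wtmt, mtmt).
#' @export
parametric_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  q1 <- scenario$q1; p1 <- 1 - q1
  s <- scenario$s; H <- scenario$H; m <- scenario$mortality
  f1 <- c(p1^2, 2 * p1 * q1, q1^2)
  w <- c(1, 1 - H * s, 1 - s)
  wbar <- sum(f1 * w)
  death <- switch(scenario$hazard,
                  competing = 1 - (1 - m) * w,
                  additive = pmin(m + (1 - w), 1))
  if (all(death == 0))
    abort_degdom("scenario produces no deaths: cases undefined",
                 class = "degdom_config_error")
  case_freqs <- f1 * death / sum(f1 * death)
  survivor_freqs <- f1 * w / wbar
  list(control_freqs = f1, case_freqs = case_freqs,
       survivor_freqs = survivor_freqs,
       fitness = w, death_prob = death, wbar = wbar)
}

# Inverse-CDF categorical sampler: each subject is a uniform draw located
# within the cumulative genotype frequency intervals.
sample_genotypes <- function(n, freqs) {
  cum <- cumsum(freqs) / sum(freqs)
  idx <- findInterval(stats::runif(n), cum[1:2]) + 1L
  tabulate(idx, nbins = 3L)
}

#' Sample a case-control genotype table from parametric frequencies
#'
#' Each subject is drawn by inverse-CDF sampling: a uniform variate is
#' located within the cumulative genotype-frequency intervals of its
#' column. Fully reproducible under `seed`.
#'
#' @param control_freqs,case_freqs Genotype frequency vectors
#'   (wtwt, wtmt, mtmt), each summing to 1.
#' @param n_controls,n_cases Numbers of subjects to draw.
#' @param seed Optional integer seed (set before drawing when non-NULL).
#' @return A [genotype_table()].
#' @export
sample_table <- function(control_freqs, case_freqs,
                         n_controls = 400L, n_cases = 400L, seed = NULL) {
  stopifnot(length(control_freqs) == 3L, length(case_freqs) == 3L,
            all(control_freqs >= 0), all(case_freqs >= 0),
            abs(sum(control_freqs) - 1) < 1e-8,
            abs(sum(case_freqs) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(as.integer(seed))
  genotype_table(sample_genotypes(n_controls, control_freqs),
                 sample_genotypes(n_cases, case_freqs))
}

#' Simulate one case-control study from a cohort scenario
#'
#' Convenience wrapper: [parametric_cohort()] then [sample_table()].
#'
#' @param scenario A [cohort_scenario()].
#' @return A [genotype_table()].
#' @export
simulate_cohort_study <- function(scenario) {
  ph <- parametric_cohort(scenario)
  sample_table(ph$control_freqs, ph$case_freqs,
               scenario$n_controls, scenario$n_cases, scenario$seed)
}

#' Sweep the cohort model over (q1, H, s) and score the h-index
#'
#' For every grid point, `replicates` case-control studies of
#' `n_cases`/`n_controls` subjects are sampled from the parametric cohort
#' and the h-index estimated from each. Per (q1, s) panel the Spearman rank
#' correlation between the true dominance H and the estimated h summarises
#' how well the index recovers the generative mode of inheritance.
#'
#' @param q1_grid Initial mutant allele frequencies (subset of
#'   `[0.05, 0.5]`).
#' @param H_grid True dominance values (subset of `[0, 1]`).
#' @param s_values Selection coefficients (default `c(0.2, 0.5)`).
#' @param replicates Studies per grid point (default 50).
#' @param n_cases,n_controls Sample sizes (default 400/400).
#' @param mortality Background mortality (default 0.05).
#' @param seed Mandatory integer seed.
#' @return List with `records` (one row per simulated study: `q1`, `s`,
#'   `H`, `replicate`, `h`, `ln_theta_co`, `ln_theta_a`) and `panels`
#'   (per (q1, s): `spearman` between H and h, and `n`). Studies whose
#'   additive log odds ratio is exactly zero yield infinite h and are kept
#'   in the records; Spearman is rank-based and unaffected.
#' @export
performance_sweep <- function(q1_grid = seq(0.05, 0.5, by = 0.05),
                              H_grid = seq(0, 1, by = 0.25),
                              s_values = c(0.2, 0.5),
                              replicates = 50L,
                              n_cases = 400L, n_controls = 400L,
                              mortality = 0.05,
                              seed) {
  if (missing(seed) || !is.numeric(seed))
    abort_degdom("an integer 'seed' is mandatory for simulation reproducibility",
                 class = "degdom_config_error")
  set.seed(as.integer(seed))
  grid <- expand.grid(q1 = q1_grid, H = H_grid, s = s_values,
                      KEEP.OUT.ATTRS = FALSE)
  recs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- cohort_scenario(grid$q1[i], grid$s[i], grid$H[i],
                          mortality = mortality,
                          n_cases = n_cases, n_controls = n_controls)
    ph <- parametric_cohort(sc)
    h <- lco <- la <- numeric(replicates)
    for (r in seq_len(replicates)) {
      tab <- sample_table(ph$control_freqs, ph$case_freqs,
                          n_controls, n_cases)
      co <- quiet_haldane(codominant_log_or(tab))
      ad <- quiet_haldane(additive_log_or(tab))
      lco[r] <- co$log_or; la[r] <- ad$log_or
      h[r] <- if (ad$log_or == 0 && co$log_or == 0) 0
              else if (ad$log_or == 0) sign(co$log_or) * Inf
              else co$log_or / abs(ad$log_or)
    }
    recs[[i]] <- data.frame(q1 = grid$q1[i], s = grid$s[i], H = grid$H[i],
                            replicate = seq_len(replicates),
                            h = h, ln_theta_co = lco, ln_theta_a = la)
  }
  records <- do.call(rbind, recs)
  panels <- do.call(rbind, lapply(split(records, records[c("q1", "s")]),
                                  function(d) {
    data.frame(q1 = d$q1[1L], s = d$s[1L],
               spearman = stats::cor(d$H, d$h, method = "spearman"),
               n = nrow(d))
  }))
  rownames(panels) <- NULL
  list(records = records, panels = panels)
}
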