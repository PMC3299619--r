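test_that("disequilibrium estimation matches hand arithmetic", {
  # ACE controls 64/94/51: p from gene counting, D = n11/n - p^2
  tab <- example_tables()$ace
  hw <- estimate_disequilibrium(tab)
  p_hand <- (2 * 64 + 94) / (2 * 209)
  expect_equal(hw$p, p_hand, tolerance = 1e-12)
  expect_equal(hw$D, 64 / 209 - p_hand^2, tolerance = 1e-12)
  expect_equal(hw$D_min, max(-p_hand^2, -(1 - p_hand)^2))
  expect_equal(hw$D_max, p_hand * (1 - p_hand))
  expect_true(hw$D >= hw$D_min && hw$D <= hw$D_max)

  # exact HWE controls: D = 0, chi2 = 0, p = 1
  hwe_tab <- genotype_table(c(81, 18, 1), c(10, 10, 10))
  hw0 <- estimate_disequilibrium(hwe_tab)
  expect_equal(hw0$D, 0, tolerance = 1e-12)
  expect_equal(hw0$chi2, 0, tolerance = 1e-12)
  expect_equal(hw0$p_hwe, 1)

  # all-heterozygote controls: p = q = 0.5, D = -0.25 = D_min
  het <- genotype_table(c(0, 40, 0), c(10, 10, 10))
  hwh <- estimate_disequilibrium(het)
  expect_equal(hwh$p, 0.5)
  expect_equal(hwh$D, -0.25)
  expect_equal(hwh$D, hwh$D_min)
})

test_that("exact HWE test agrees with the chi-squared test in calibration", {
  # large balanced sample near HWE: the two tests agree on the verdict
  tab <- genotype_table(c(360, 480, 160), c(10, 10, 10))
  chisq <- estimate_disequilibrium(tab, "chisq")
  exact <- estimate_disequilibrium(tab, "exact")
  expect_gt(chisq$p_hwe, 0.5)
  expect_gt(exact$p_hwe, 0.5)
  # strong heterozygote excess: both reject
  bad <- genotype_table(c(10, 200, 10), c(10, 10, 10))
  expect_lt(estimate_disequilibrium(bad, "chisq")$p_hwe, 1e-6)
  expect_lt(estimate_disequilibrium(bad, "exact")$p_hwe, 1e-6)
})

test_that("Weir-model round trip reconstructs the control counts", {
  set.seed(61)
  for (i in 1:20) {
    tab <- random_positive_table()
    hw <- estimate_disequilibrium(tab)
    rebuilt <- hw$n_controls * weir_frequencies_for_test(hw$p, hw$D)
    expect_equal(unname(rebuilt), unname(tab$counts[, "controls"]),
                 tolerance = 1e-8)
  }
})

test_that("parametric contrasts reduce to plain odds ratios at D = 0", {
  cases <- c(40, 80, 30)
  p <- 0.7; q <- 0.3; n <- 500
  b <- biased_contrasts(cases, p, 0, n)
  # plain odds ratios from HWE-proportion control counts
  n11 <- n * p^2; n21 <- n * 2 * p * q; n31 <- n * q^2
  expect_equal(b$theta_a, (cases[3L] * n11) / (cases[1L] * n31),
               tolerance = 1e-12)
  expect_equal(b$theta_co, (cases[2L] * (n11 + n31)) / (n21 * (cases[1L] + cases[3L])),
               tolerance = 1e-12)
})

test_that("homozygote-excess endpoint and bound violations behave analytically", {
  cases <- c(40, 80, 30)
  p <- 0.8; q <- 0.2
  at_max <- biased_contrasts(cases, p, p * q)
  expect_equal(at_max$theta_a, (cases[3L] / cases[1L]) * (p / q),
               tolerance = 1e-12)
  expect_false(is.finite(at_max$theta_co))  # 2pq - 2D = 0: divergence
  expect_error(biased_contrasts(cases, p, p * q + 0.01),
               class = "degdom_bound_violation_error")
  expect_error(biased_contrasts(cases, p, -q^2 - 0.01),
               class = "degdom_bound_violation_error")
})

test_that("the D-sandwich on the contrasts holds on a dense admissible grid", {
  # for p >= 3q the additive factor is bounded below by p/q (at D = pq) and
  # the co-dominant odds ratio by its plain-HWE floor (at D = -q^2);
  # the additive bound needs no maf restriction, the co-dominant one does
  cases <- c(50, 60, 25)
  for (q in c(0.05, 0.1, 0.2, 0.25)) {
    p <- 1 - q
    lo <- -q^2 + 1e-9; hi <- p * q - 1e-9
    grid <- seq(lo, hi, length.out = 201L)
    th <- vapply(grid, function(D) {
      b <- biased_contrasts(cases, p, D)
      c(b$theta_a, b$theta_co)
    }, numeric(2L))
    expect_true(all(th[1L, ] >= (cases[3L] / cases[1L]) * (p / q) - 1e-9))
    expect_true(all(th[2L, ] >= cases[2L] / (cases[1L] + cases[3L]) - 1e-9))
    # additive factor decreases in D, co-dominant increases
    expect_true(all(diff(th[1L, ]) < 0))
    expect_true(all(diff(th[2L, ]) > 0))
  }
})

test_that("|h| inflates monotonically as homozygote excess D grows", {
  cases <- c(40, 80, 30)
  p <- 0.8; q <- 0.2
  Ds <- seq(0, p * q * 0.95, length.out = 25L)
  habs <- vapply(Ds, function(D) abs(biased_contrasts(cases, p, D)$h),
                 numeric(1L))
  expect_true(all(diff(habs) > 0))
})

test_that("disequilibrium bias simulation shows the stratification bias", {
  pos <- simulate_hwe_bias(400L, "positive", seed = 71)
  expect_identical(nrow(pos), 400L)
  expect_true(all(pos$D >= 0.005))
  expect_true(all(pos$maf >= 0.05 & pos$maf <= 0.40))
  # D > 0 upward-biases |h| on average
  expect_gt(mean(abs(pos$h_biased)), mean(abs(pos$h_ref)))

  neg <- simulate_hwe_bias(400L, "negative", seed = 71)
  expect_true(all(neg$D <= -0.005))
  # heterozygote excess flips the sign of h in some replicates
  expect_gt(sum(neg$sign_flip), 0L)

  # determinism under the seed
  pos2 <- simulate_hwe_bias(400L, "positive", seed = 71)
  expect_identical(pos, pos2)

  expect_error(simulate_hwe_bias(10L, "positive", seed = 1,
                                 maf_window = c(0.001, 0.004)),
               class = "degdom_config_error")
  expect_error(simulate_hwe_bias(10L, "positive"),
               class = "degdom_config_error")
})
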