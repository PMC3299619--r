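test_that("additive and co-dominant log odds ratios match direct arithmetic", {
  tabs <- example_tables()

  # ACE: ln[(82*64)/(34*51)] and Woolf variance, straight off the counts
  ace_add <- additive_log_or(tabs$ace)
  expect_equal(ace_add$log_or, log((82 * 64) / (34 * 51)), tolerance = 1e-12)
  expect_equal(ace_add$variance, 1 / 82 + 1 / 64 + 1 / 34 + 1 / 51,
               tolerance = 1e-12)
  expect_equal(ace_add$z, ace_add$log_or / sqrt(ace_add$variance))

  # ADH2 printed values at 2 d.p.
  expect_equal(round(additive_log_or(tabs$adh2)$log_or, 2), 2.08)
  expect_equal(round(codominant_log_or(tabs$adh2)$log_or, 2), 0.48)

  # BDNF printed co-dominant value
  expect_equal(round(codominant_log_or(tabs$bdnf)$log_or, 2), -0.54)
})

test_that("identity and symmetry tables give zero log odds ratios", {
  flat <- genotype_table(c(10, 5, 10), c(10, 5, 10))
  expect_equal(additive_log_or(flat)$log_or, 0)
  expect_equal(additive_log_or(flat)$z, 0)
  expect_equal(codominant_log_or(flat)$log_or, 0)
})

test_that("contrast coefficient vectors are the orthogonal pair", {
  tab <- random_positive_table()
  add <- additive_log_or(tab)
  co <- codominant_log_or(tab)
  expect_identical(add$coefficients, c(1, 0, -1))
  expect_identical(co$coefficients, c(-0.5, 1, -0.5))
  expect_equal(sum(add$coefficients * co$coefficients), 0)
  expect_equal(sum(add$coefficients), 0)
  expect_equal(sum(co$coefficients), 0)
})

test_that("all four contrasts agree with the brute-force 2x2 collapse oracle", {
  set.seed(11)
  for (i in 1:50) {
    tab <- random_positive_table()
    for (ct in c("additive", "co-dominant", "dominant", "recessive")) {
      est <- genotype_contrast(tab, ct)
      orc <- oracle_2x2(tab, ct)
      expect_equal(est$log_or, orc$log_or, tolerance = 1e-12)
      expect_equal(est$variance, orc$variance, tolerance = 1e-12)
      expect_true(est$p_two_sided > 0 && est$p_two_sided <= 1)
      expect_true(est$variance > 0)
    }
  }
})

test_that("row, column and scaling symmetries hold", {
  set.seed(23)
  for (i in 1:25) {
    tab <- random_positive_table()
    n <- tab$counts

    # wtwt <-> mtmt swap negates the additive, fixes the co-dominant
    swapped <- genotype_table(n[3:1, 1L], n[3:1, 2L])
    expect_equal(additive_log_or(swapped)$log_or,
                 -additive_log_or(tab)$log_or, tolerance = 1e-12)
    expect_equal(codominant_log_or(swapped)$log_or,
                 codominant_log_or(tab)$log_or, tolerance = 1e-12)

    # case/control swap negates both, variances unchanged
    flipped <- genotype_table(n[, 2L], n[, 1L])
    for (f in list(additive_log_or, codominant_log_or)) {
      expect_equal(f(flipped)$log_or, -f(tab)$log_or, tolerance = 1e-12)
      expect_equal(f(flipped)$variance, f(tab)$variance, tolerance = 1e-12)
    }

    # scaling all counts by m fixes the log-OR, divides the variance by m
    m <- sample(2:7, 1L)
    scaled <- genotype_table(m * n[, 1L], m * n[, 2L])
    for (f in list(additive_log_or, codominant_log_or)) {
      expect_equal(f(scaled)$log_or, f(tab)$log_or, tolerance = 1e-12)
      expect_equal(f(scaled)$variance, f(tab)$variance / m, tolerance = 1e-12)
    }
  }
})

test_that("continuity policy governs zero collapsed cells", {
  tab <- genotype_table(c(50, 30, 0), c(40, 35, 10))
  expect_error(additive_log_or(tab, correction = "strict"),
               class = "degdom_zero_cell_error")
  expect_warning(est <- additive_log_or(tab, correction = "haldane"),
                 class = "degdom_haldane_warning")
  expect_true(est$correction_applied)
  # Haldane: +0.5 on every collapsed cell
  expect_equal(est$log_or, log((10.5 * 50.5) / (40.5 * 0.5)), tolerance = 1e-12)
  expect_equal(est$variance, 1 / 10.5 + 1 / 50.5 + 1 / 40.5 + 1 / 0.5,
               tolerance = 1e-12)
  # the co-dominant aggregates are positive here: no correction, no warning
  expect_no_warning(co <- codominant_log_or(tab))
  expect_false(co$correction_applied)
  # quiet_haldane muffles only the correction warning
  expect_no_warning(quiet_haldane(additive_log_or(tab)))
})

test_that("positive additive log odds ratio means mtmt has higher case odds", {
  riskier <- genotype_table(c(100, 50, 10), c(50, 50, 40))
  expect_gt(additive_log_or(riskier)$log_or, 0)
  protective <- genotype_table(c(50, 50, 40), c(100, 50, 10))
  expect_lt(additive_log_or(protective)$log_or, 0)
})
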