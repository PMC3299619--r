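test_that("h-index reproduces the worked examples and edge cases", {
  tabs <- example_tables()
  h_adh2 <- h_index(codominant_log_or(tabs$adh2), additive_log_or(tabs$adh2))
  expect_equal(round(h_adh2, 2), 0.23)
  h_bdnf <- h_index(codominant_log_or(tabs$bdnf), additive_log_or(tabs$bdnf))
  expect_equal(round(h_bdnf, 2), -1.82)

  # perfect additivity: n22 (n11+n31) = n21 (n12+n32) makes ln(theta_co) = 0
  exact <- genotype_table(c(50, 25, 50), c(20, 25, 80))
  expect_equal(codominant_log_or(exact)$log_or, 0)
  expect_equal(h_index(codominant_log_or(exact), additive_log_or(exact)), 0)

  # additive log-OR exactly zero: infinite h carrying the co-dominant sign
  bal <- genotype_table(c(50, 20, 50), c(30, 60, 30))
  expect_equal(additive_log_or(bal)$log_or, 0)
  expect_identical(h_index(codominant_log_or(bal), additive_log_or(bal)), Inf)

  # both zero: undefined
  flat <- genotype_table(c(10, 5, 10), c(10, 5, 10))
  expect_error(h_index(codominant_log_or(flat), additive_log_or(flat)),
               class = "degdom_undefined_h_error")
})

test_that("k-test matches the hand-computed oracle on the printed BDNF counts", {
  # all quantities below are plain arithmetic on the printed table
  # (controls 208/131/11, cases 229/83/9), independent of the package
  ln_co <- log(83 * (208 + 11) / (131 * (229 + 9)))
  ln_a <- log(9 * 208 / (229 * 11))
  var_co <- 1 / 83 + 1 / (208 + 11) + 1 / 131 + 1 / (229 + 9)
  var_a <- 1 / 9 + 1 / 208 + 1 / 229 + 1 / 11
  k_hand <- ln_co + ln_a                 # ln(theta_a) < 0 branch
  var_hand <- var_co + var_a * (1 - 2 / pi)
  z_hand <- k_hand / sqrt(var_hand)

  tab <- example_tables()$bdnf
  kt <- k_test(codominant_log_or(tab), additive_log_or(tab), "under")
  expect_equal(kt$k, k_hand, tolerance = 1e-12)
  expect_equal(kt$var_k, var_hand, tolerance = 1e-12)
  expect_equal(kt$z, z_hand, tolerance = 1e-12)
  expect_equal(kt$p_one_sided, pnorm(z_hand), tolerance = 1e-12)
  # frozen oracle values (hand calculation)
  expect_equal(kt$k, -0.8364103, tolerance = 1e-6)
  expect_equal(kt$var_k, 0.1051937, tolerance = 1e-6)
  expect_equal(kt$p_one_sided, 0.0049566, tolerance = 1e-4)
})

test_that("k-test boundary and sign symmetries", {
  # ln(theta_co) = |ln(theta_a)| exactly (both ln 2): k = 0, p = 0.5
  tab <- genotype_table(c(100, 30, 50), c(25, 20, 25))
  co <- codominant_log_or(tab); add <- additive_log_or(tab)
  expect_equal(co$log_or, log(2), tolerance = 1e-12)
  expect_equal(add$log_or, log(2), tolerance = 1e-12)
  kt <- k_test(co, add, "over")
  expect_equal(kt$k, 0, tolerance = 1e-12)
  expect_equal(kt$p_one_sided, 0.5, tolerance = 1e-12)

  # both sign branches collapse to k = ln(theta_co) - |ln(theta_a)|; this
  # also documents the deliberate asymmetry of the under-dominance case,
  # where the null boundary sits at h = +1 rather than h = -1
  set.seed(53)
  for (i in 1:20) {
    t1 <- random_positive_table()
    co <- codominant_log_or(t1); add <- additive_log_or(t1)
    for (dir in c("over", "under")) {
      kt <- k_test(co, add, dir)
      expect_equal(kt$k, co$log_or - abs(add$log_or), tolerance = 1e-12)
      expect_equal(kt$var_k,
                   co$variance + add$variance * (1 - 2 / pi),
                   tolerance = 1e-12)
    }
    # the two directions are complementary one-sided tails
    expect_equal(k_test(co, add, "over")$p_one_sided +
                 k_test(co, add, "under")$p_one_sided, 1, tolerance = 1e-12)
  }
})

test_that("the hypothesis ladder classifies the three worked examples", {
  tabs <- example_tables()
  ace <- classify_dominance(tabs$ace, alpha = 0.05)
  expect_identical(ace$mode, "non-dominance")
  expect_equal(round(ace$codominant_p, 2), 0.75)
  expect_true(is.na(ace$p_k_one_sided))
  expect_false(is.na(ace$h))  # h reported even under non-dominance

  adh2 <- classify_dominance(tabs$adh2, alpha = 0.05)
  expect_identical(adh2$mode, "dominance-of-mt")
  expect_equal(round(adh2$h, 2), 0.23)

  bdnf <- classify_dominance(tabs$bdnf, alpha = 0.05)
  expect_identical(bdnf$mode, "under-dominance")
  expect_equal(round(bdnf$h, 2), -1.82)
  expect_lt(bdnf$p_k_one_sided, 0.05)
  expect_equal(bdnf$half_normal_factor, 1 - 2 / pi)

  # an alpha between the co-dominant p (0.0014) and the k-test p (0.0050)
  # stops the BDNF ladder at the unresolved rung
  strict <- classify_dominance(tabs$bdnf, alpha = 0.003)
  expect_identical(strict$mode, "dominance-unresolved")
})

test_that("classification is stable or sharpens under 10x count scaling", {
  tabs <- example_tables()
  for (tab in tabs) {
    big <- genotype_table(10L * tab$counts[, 1L], 10L * tab$counts[, 2L],
                          labels = tab$labels)
    small_call <- classify_dominance(tab)
    big_call <- classify_dominance(big)
    # h is scale-invariant; decisions only sharpen with more data
    expect_equal(big_call$h, small_call$h, tolerance = 1e-12)
    if (small_call$mode != "non-dominance")
      expect_lt(big_call$codominant_p, small_call$codominant_p)
  }
})

test_that("h negates under a case-control column swap", {
  set.seed(59)
  for (i in 1:20) {
    tab <- random_positive_table()
    n <- tab$counts
    sw <- genotype_table(n[, 2L], n[, 1L])
    h1 <- h_index(codominant_log_or(tab), additive_log_or(tab))
    h2 <- h_index(codominant_log_or(sw), additive_log_or(sw))
    expect_equal(h2, -h1, tolerance = 1e-12)
  }
})
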