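test_that("2x2 tests handle degenerate and balanced tables", {
  res <- two_by_two_test(10, 10, 10, 10, "chi2_cc")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1L)
  expect_error(two_by_two_test(5, 0, 3, 0, "chi2_cc"), "margin")
  expect_equal(two_by_two_test(5, 0, 3, 0, "fisher")$p_value, 1)
  expect_error(two_by_two_test(-1, 2, 3, 4), "nonnegative")
  # full enumeration over x in {0,1,2}: (2,0,0,2) has p = 1/3
  expect_equal(two_by_two_test(2, 0, 0, 2, "fisher")$p_value, 1 / 3)
})

test_that("2x2 p-values are invariant to consistent relabeling", {
  set.seed(11)
  for (i in 1:20) {
    t4 <- rpois(4, 8)
    if (any(rowSums(matrix(t4, 2)) == 0) || any(colSums(matrix(t4, 2)) == 0))
      next
    for (m in c("chi2_cc", "fisher")) {
      p0 <- two_by_two_test(t4[1], t4[2], t4[3], t4[4], m)$p_value
      p_rows <- two_by_two_test(t4[3], t4[4], t4[1], t4[2], m)$p_value
      p_cols <- two_by_two_test(t4[2], t4[1], t4[4], t4[3], m)$p_value
      expect_equal(p0, p_rows)
      expect_equal(p0, p_cols)
    }
  }
})

test_that("fisher matches hypergeometric enumeration on random tables", {
  set.seed(21)
  for (i in 1:50) {
    t4 <- rpois(4, 6) + c(1, 0, 0, 1)
    p <- two_by_two_test(t4[1], t4[2], t4[3], t4[4], "fisher")$p_value
    expect_equal(p, fisher_oracle(t4[1], t4[2], t4[3], t4[4]),
                 tolerance = 1e-10)
  }
})

test_that("rank-sum comparison: exact small-sample p and monotone power", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(rank_sum_test(c(2, 2), c(2, 2))$p_value, 1)
  # p decreases monotonically as one sample shifts away
  set.seed(31)
  x <- rnorm(40)
  p_shift <- vapply(c(0.2, 0.8, 1.6), function(d)
    rank_sum_test(x, x + d)$p_value, numeric(1))
  expect_true(all(diff(p_shift) < 0))
  expect_error(rank_sum_test(numeric(0), 1), "nonempty")
})

test_that("friedman test: closed-form small example and tie handling", {
  m <- matrix(rep(c(1, 2, 3), 3), nrow = 3, byrow = TRUE)
  res <- friedman_rm_test(m)
  expect_equal(res$statistic, 6)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.0498, tolerance = 1e-3)
  # identical values in every block: no evidence, p = 1
  res0 <- friedman_rm_test(matrix(5, nrow = 3, ncol = 4))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(friedman_rm_test(matrix(1, 2, 2)), "k >= 3")
  expect_error(friedman_rm_test(matrix(c(1, NA, 3, 4, 5, NA), 2, 3)),
               "complete blocks")
})

test_that("friedman exact permutation p matches a Monte-Carlo oracle", {
  set.seed(41)
  m <- matrix(rnorm(12), nrow = 4, ncol = 3)
  res <- friedman_rm_test(m, exact = TRUE)
  # independent oracle: random within-block permutations of the data
  stat_obs <- friedman_rm_test(m)$statistic
  draws <- 4000
  hits <- 0
  for (i in seq_len(draws)) {
    mm <- t(apply(m, 1, sample))
    if (friedman_rm_test(mm)$statistic >= stat_obs - 1e-12) hits <- hits + 1
  }
  mc_p <- hits / draws
  mc_se <- sqrt(mc_p * (1 - mc_p) / draws)
  expect_lt(abs(res$p_value - mc_p), 3 * mc_se + 1e-6)
})

test_that("signed-rank post hocs: exact p, symmetry, zeros, Bonferroni flags", {
  expect_equal(signed_rank_test(c(1, 2, 3))$p_value, 0.25)
  expect_equal(signed_rank_test(c(-2, -1, 1, 2))$p_value, 1)
  expect_warning(res <- signed_rank_test(c(0, 0, 0)), "zero")
  expect_equal(res$p_value, 1)
  m <- cbind(T0 = c(5, 4, 5, 3, 4, 5), T6 = c(2, 1, 3, 0, 2, 2),
             T12 = c(1, 0, 2, 0, 1, 1))
  ph <- signed_rank_posthoc(m, alpha = 0.05)
  expect_equal(nrow(ph), 3)
  expect_equal(attr(ph, "threshold"), 0.05 / 3)
  expect_equal(ph$significant, ph$p_value < 0.05 / 3)
})

test_that("signed-rank exact p matches sign-flip enumeration", {
  set.seed(51)
  for (n in c(5, 6, 8)) {
    for (i in 1:5) {
      d <- round(rnorm(n, 0.3), 2)
      d <- d[d != 0]
      if (anyDuplicated(abs(d))) next
      expect_equal(signed_rank_test(d)$p_value, signed_rank_oracle(d),
                   tolerance = 1e-10)
    }
  }
})

test_that("bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 14), 0.05 / 14)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("change summary aligns visits to nominal months after CYC start", {
  co <- tiny_cohort()   # patient A treated at month 1, visits 0.5,1,3,7,14
  cs <- change_summary(co, "das", nominal = c(0, 6, 12), window = 2)
  expect_equal(cs$summary$n, c(1, 1, 1))
  expect_equal(unname(cs$blocks["A", ]), c(4, 2, 1))  # visits at 1, 7, 14
  # constant measure: identical medians wherever observed
  co2 <- co; co2$visits$das <- 3
  cs2 <- change_summary(co2, "das", nominal = c(0, 6, 12), window = 2)
  expect_true(all(cs2$summary$median == 3))
})

test_that("planted graded improvement yields monotone decreasing DAS medians", {
  cfg <- fast_config(seed = 77, n = 150,
                     effect_das = c(le6 = -0.8, m6_12 = -1.4, gt12 = -2),
                     missingness = c(das = 0, pga = 0, cmas = 0, gc_dose = 0))
  co <- simulate_cohort(cfg)$cohort
  cs <- change_summary(co, "das", nominal = c(0, 6, 12, 24))
  med <- cs$summary$median
  expect_true(all(diff(med) <= 0))
  expect_lt(med[4], med[1])
  expect_s3_class(cs$friedman, "cyc_test")
  expect_lt(cs$friedman$p_value, 0.05)
})

test_that("change summary missing fractions reproduce planted rates", {
  cfg <- fast_config(seed = 88, n = 250, frac_treated_target = 0.5)
  co <- simulate_cohort(cfg)$cohort
  cs <- change_summary(co, "pga", nominal = c(0, 6, 12))
  # pga cells are missing at ~25%; alignment failures add a little
  expect_true(all(cs$summary$pct_missing > 10))
  expect_true(all(cs$summary$pct_missing < 45))
})
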