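test_that("with unit weights and one visit per patient the fit is OLS", {
  set.seed(61)
  n <- 120
  p <- do.call(rbind, lapply(seq_len(n), function(i) {
    treated <- i <= 40
    make_patient(sprintf("P%03d", i),
                 cyc_start = if (treated) 1 else NA,
                 cyc_stop = if (treated) 6 else NA)
  }))
  t_obs <- runif(n, 0, 30)
  v <- do.call(rbind, lapply(seq_len(n), function(i) {
    vv <- make_visits(sprintf("P%03d", i), t_obs[i],
                      das = round(runif(1, 0, 5), 1))
    vv$on_cyc <- !is.na(p$cyc_start_months[i]) &&
      t_obs[i] >= 1 && t_obs[i] < 6
    vv
  }))
  co <- cohort_table(p, v)
  fit <- fit_weighted_outcome(co, NULL, "das")
  vf <- cycmsm:::visit_frame(co)
  ols <- lm(das ~ t_months + st, data = droplevels(vf))
  expect_equal(fit$estimates$estimate[seq_along(coef(ols))],
               unname(coef(ols)), tolerance = 1e-8)
})

test_that("estimates are invariant to patient ordering", {
  cfg <- fast_config(seed = 67, n = 100,
                     missingness = c(das = 0, pga = 0, cmas = 0, gc_dose = 0))
  co <- simulate_cohort(cfg)$cohort
  perm <- sample(nrow(co$patients))
  co2 <- cohort_table(co$patients[perm, ], co$visits[rev(seq_len(nrow(co$visits))), ])
  f1 <- fit_weighted_outcome(co, NULL, "das")$estimates
  f2 <- fit_weighted_outcome(co2, NULL, "das")$estimates
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-8)
})

test_that("rubin pooling reproduces the closed-form worked example", {
  est <- c(1.0, 1.2, 1.1, 0.9, 1.3)
  fits <- lapply(est, function(q) {
    structure(list(estimates = data.frame(term = "stcyc_gt_12mo",
                                          estimate = q, robust_se = 0.2,
                                          estimable = TRUE),
                   outcome = "das", n_patients = 200, n_visits = 1000,
                   rank = 5), class = "outcome_fit")
  })
  pe <- pool_rubin(fits)
  expect_equal(pe$estimate, 1.1, tolerance = 1e-12)
  expect_equal(pe$W, 0.04, tolerance = 1e-12)
  expect_equal(pe$B, 0.025, tolerance = 1e-12)
  expect_equal(pe$T, 0.07, tolerance = 1e-12)
  expect_equal(pe$se, sqrt(0.07), tolerance = 1e-12)
  # identical estimates: no between-imputation variance
  same <- lapply(fits, function(f) { f$estimates$estimate <- 1.1; f })
  pe0 <- pool_rubin(same)
  expect_equal(pe0$B, 0)
  expect_equal(pe0$T, pe0$W)
  # perturbing one set strictly inflates the pooled SE
  pert <- same; pert[[3]]$estimates$estimate <- 1.6
  expect_gt(pool_rubin(pert)$se, pe0$se)
  # mismatched coefficient sets are refused
  bad <- fits
  bad[[2]]$estimates$term <- "stcyc_le_6mo"
  expect_error(pool_rubin(bad), "mismatched")
  expect_error(pool_rubin(fits[1]), "m >= 2")
})

test_that("rubin identity T = W + (1 + 1/m) B holds on pipeline output", {
  cfg <- fast_config(seed = 71, n = 100)
  co <- simulate_cohort(cfg)$cohort
  res <- run_msm(co, outcomes = "das", m = 4, seed = 5)
  pe <- res$pooled$das
  ok <- pe$estimable
  expect_equal(pe$T[ok], pe$W[ok] + (1 + 1 / 4) * pe$B[ok],
               tolerance = 1e-12)
  expect_true(all(pe$ci_low[ok] <= pe$estimate[ok] &
                    pe$estimate[ok] <= pe$ci_high[ok]))
})

test_that("run_msm completes end to end and reports all contrasts", {
  cfg <- fast_config(seed = 73, n = 100)
  co <- simulate_cohort(cfg)$cohort
  res <- run_msm(co, m = 3, seed = 8)
  ft <- forest_table(res)
  expect_equal(nrow(ft), 9)   # three outcomes x three categories
  expect_setequal(unique(ft$outcome), c("das", "pga", "cmas"))
  expect_equal(res$m, 3)
  expect_true(all(is.finite(res$weights_summary$mean_raw) &
                    res$weights_summary$mean_raw > 0))
  expect_output(print(res), "msm_result")
})

test_that("a cohort with nobody treated reports inestimable contrasts", {
  cfg <- fast_config(seed = 79, n = 60)
  co <- simulate_cohort(cfg)$cohort
  co <- cohort_table(
    transform(co$patients, cyc_start_months = NA_real_,
              cyc_stop_months = NA_real_),
    transform(co$visits, on_cyc = FALSE))
  res <- run_msm(co, outcomes = "das", m = 2, seed = 3)
  ft <- forest_table(res)
  expect_true(all(is.na(ft$coef)))
  expect_true(all(ft$signif == "-"))
})

test_that("unobserved categories are flagged, not silently dropped", {
  # treated patients observed only up to 10 months after start: the
  # >12-months category never occurs
  p <- rbind(make_patient("A", cyc_start = 1, cyc_stop = 6),
             make_patient("B"), make_patient("D"))
  va <- make_visits("A", c(0.5, 2, 5, 9), das = c(4, 3, 2, 2))
  va$on_cyc <- c(FALSE, TRUE, TRUE, FALSE)
  vb <- make_visits("B", c(0.3, 6, 14, 20), das = 2)
  vd <- make_visits("D", c(0.4, 3, 12, 22), das = 3)
  co <- cohort_table(p, rbind(va, vb, vd))
  fit <- fit_weighted_outcome(co, NULL, "das")
  est <- fit$estimates
  expect_false(est$estimable[est$term == "stcyc_gt_12mo"])
  expect_true(est$estimable[est$term == "stcyc_le_6mo"])
})
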