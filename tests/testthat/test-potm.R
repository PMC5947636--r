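# Complete-case simulated cohort used across the PoTM tests.
potm_cohort <- function(seed = 17, n = 250, ...) {
  cfg <- fast_config(seed = seed, n = n,
                     missingness = c(das = 0, pga = 0, cmas = 0, gc_dose = 0),
                     ...)
  simulate_cohort(cfg)$cohort
}

test_that("intercept-only sub-models reduce to empirical hazards", {
  co <- potm_cohort()
  base <- fit_baseline_model(co, covars = character(0))
  rf <- cycmsm:::risk_frame(co)
  first <- rf[rf$visit_index == 1, ]
  expect_equal(unname(cycmsm:::predict_potm(base, first)[1]),
               mean(first$y_base), tolerance = 1e-8)
  init <- fit_initiation_model(co, covars = character(0))
  atrisk <- rf[rf$in_init, ]
  expect_equal(unname(cycmsm:::predict_potm(init, atrisk)[1]),
               mean(atrisk$y_init), tolerance = 1e-8)
})

test_that("initiation model recovers the planted indication log-odds", {
  # hazard: logit p = a + b * (skin-dominant severity composite) + g * t;
  # with complete scores the implied per-score slopes are 0.5*b/0.8,
  # 0.25*b/1.8, -0.25*b/9 and the time slope is g
  co <- potm_cohort(seed = 19, n = 2000, confounding_strength = 1)
  fit <- fit_initiation_model(co)
  tab <- coef_table(fit)
  pick <- function(term) tab[tab$term == term, ]
  for (chk in list(list("das", 0.625), list("pga", 0.25 / 1.8),
                   list("cmas", -0.25 / 9), list("t_months", -0.5))) {
    row <- pick(chk[[1]])
    expect_lt(abs(row$estimate - chk[[2]]), 2 * row$robust_se)
  }
  # predictions increase with severity when the planted slope is positive
  expect_gt(pick("das")$estimate, 0)
  expect_gt(pick("pga")$estimate, 0)
  expect_lt(pick("cmas")$estimate, 0)
})

test_that("baseline model predictions are strictly inside (0, 1)", {
  co <- potm_cohort(seed = 23)
  fits <- fit_potm(co)
  rf <- cycmsm:::risk_frame(co)
  p <- cycmsm:::predict_potm(fits$baseline, rf[rf$visit_index == 1, ])
  expect_true(all(p > 0 & p < 1))
})

test_that("protocolized stopping falls back to a banded hazard", {
  # every course exactly 6 months, visits on a fixed grid: stopping is
  # deterministic in time on treatment
  p <- do.call(rbind, lapply(1:24, function(i)
    make_patient(sprintf("S%02d", i), cyc_start = 1, cyc_stop = 7)))
  v <- do.call(rbind, lapply(1:24, function(i) {
    vv <- make_visits(sprintf("S%02d", i), c(0.5, 1, 3, 5, 8, 10),
                      das = 3, pga = 5, cmas = 25)
    vv$on_cyc <- c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE)
    vv
  }))
  co <- cohort_table(p, v)
  fit <- fit_discontinuation_model(co)
  expect_equal(fit$method, "banded")
  tab <- fit$object$table
  expect_true(all(tab$hazard > 0 & tab$hazard < 1))
  # stop probability ~1 in the band where every course ends
  expect_gt(tab$hazard[tab$band == "[6,8)"], 0.9)
  expect_lt(tab$hazard[tab$band == "[0,4)"], 0.1)
})

test_that("fitted stop probability increases with time on treatment", {
  co <- potm_cohort(seed = 29, n = 400, frac_treated_target = 0.4)
  fit <- fit_discontinuation_model(co)
  rf <- cycmsm:::risk_frame(co)
  df <- rf[rf$in_stop, ]
  newdat <- df[rep(1, 2), ]
  newdat$tot <- c(3, 7)
  pr <- cycmsm:::predict_potm(fit, newdat)
  expect_gt(pr[2], pr[1])
})

test_that("degenerate risk sets raise informative errors", {
  co <- tiny_cohort()
  never <- cohort_table(
    transform(co$patients, cyc_start_months = NA_real_,
              cyc_stop_months = NA_real_),
    transform(co$visits, on_cyc = FALSE))
  expect_error(fit_discontinuation_model(never), "risk set is empty")
  expect_error(fit_initiation_model(never), "trivially 1")
})

test_that("observed-state probabilities follow the treatment path", {
  co <- tiny_cohort()
  co <- apply_eligibility(co)  # A treated (start 1, stop 6.5), B never
  ctl <- potm_control(numerator_covars = character(0))
  fits <- fit_potm(co, ctl, numerator = TRUE)   # intercept-only sub-models
  pr <- predict_treatment_probabilities(fits, co)
  a <- pr[pr$patient_id == "A", ]
  # A: off at 0.5, starts at 1, continues at 3, stops by 7, post at 14
  expect_equal(a$state, c("baseline_off", "start", "continue", "stop",
                          "post_cyc"))
  expect_equal(a$prob[5], 1)
  b <- pr[pr$patient_id == "B", ]
  expect_equal(b$state, c("baseline_off", rep("no_start", 3)))
  # intercept-only: probabilities depend only on risk-set membership
  rf <- cycmsm:::risk_frame(co)
  p_init_hat <- mean(rf$y_init[rf$in_init])
  expect_equal(b$prob[-1], rep(1 - p_init_hat, 3), tolerance = 1e-8)
  # all modelled probabilities strictly positive
  expect_true(all(pr$prob > 0))
})

test_that("positivity holds on a default synthetic cohort", {
  co <- potm_cohort(seed = 31)
  fits <- fit_potm(co)
  pr <- predict_treatment_probabilities(fits, co)
  expect_true(all(pr$prob > 0 & pr$prob <= 1))
  mod <- pr$state != "post_cyc"
  expect_true(all(pr$prob[mod] < 1))
})
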