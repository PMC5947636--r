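#' Configuration for the synthetic cohort generator
#'
#' Builds the full parameter set of the generator.  Defaults emulate the
#' registry conditions the pipeline is designed for: 200 incident patients
#' of whom ~28% receive a single noncontinuous cyclophosphamide course
#' (median duration 5.2 months, spread matching an IQR of 4.6-6.5 months)
#' starting early after diagnosis; severity-driven initiation (confounding
#' by indication); irregular visits, denser in the first year; item
#' missingness in PGA/CMAS/glucocorticoid dose at the registry's observed
#' rates, with the skin score never missing.
#'
#' Planted treatment effects are additive shifts of the observed scores per
#' treatment-recency category `(le6, m6_12, gt12)`; defaults plant the
#' benchmark effects of -1.19 DAS units and -0.66 PGA units for courses
#' started more than 12 months ago, and no CMAS effect.
#'
#' The initiation-hazard intercept is calibrated at configuration time so
#' that the expected ever-treated fraction equals `frac_treated_target`:
#' the calibration solves `E[1 - prod_j(1 - p_j)] = target` over a bank of
#' latent severity/visit paths simulated with a fixed internal seed, so it
#' is deterministic given the configuration.
#'
#' @param n_patients number of patients (default 200).
#' @param frac_treated_target target proportion ever treated (default 0.28).
#' @param effect_das,effect_pga,effect_cmas length-3 numeric vectors
#'   `(le6, m6_12, gt12)` of additive effects on the observed score.
#' @param confounding_strength log-odds of initiation per unit latent
#'   severity (default 1; 0 = randomized treatment).
#' @param init_time_decay log-odds of initiation per month since diagnosis
#'   (default -0.5: initiation concentrates in the first weeks after
#'   diagnosis, median about one month).
#' @param visit_rate_year1,visit_rate_later mean visits per year in the
#'   first year and afterwards.
#' @param followup_years mean follow-up (years); per-patient follow-up is
#'   uniform on (2 years, 2*mean - 2 years).
#' @param missingness named probabilities for `das`, `pga`, `cmas`,
#'   `gc_dose` item missingness (completely at random by default).
#' @param informative_missingness when `TRUE`, missingness probability for
#'   pga/cmas/gc_dose increases with latent severity (sensitivity switch).
#' @param cyc_duration_meanlog,cyc_duration_sdlog lognormal course-length
#'   parameters (defaults give median 5.2 months and IQR ~4.6-6.5).
#' @param cyc_duration_range truncation range for course length, months.
#' @param severity_sd_patient SD of the patient-specific severity set point.
#' @param severity_sd_visit stationary SD of the within-patient
#'   mean-reverting deviation.
#' @param severity_ar autocorrelation of the deviation over one month.
#' @param score_anchors named mid-severity anchors of the score transforms;
#'   defaults place the baseline medians near the registry's printed values
#'   (skin score ~4 of 5, global score ~5-6 of 10, muscle score ~20-30 of
#'   52 in the sicker patients).
#' @param score_noise named SDs of measurement noise for `das`, `pga`, `cmas`.
#' @param seed master seed; fixed seed gives a bit-identical cohort.
#' @return an object of class `sim_config` (a list), with the calibrated
#'   initiation intercept in `$init_intercept`.
#' @export
sim_config <- function(n_patients = 200,
                       frac_treated_target = 0.28,
                       effect_das = c(le6 = 0, m6_12 = 0, gt12 = -1.19),
                       effect_pga = c(le6 = 0, m6_12 = 0, gt12 = -0.66),
                       effect_cmas = c(le6 = 0, m6_12 = 0, gt12 = 0),
                       confounding_strength = 1,
                       init_time_decay = -0.5,
                       visit_rate_year1 = 10,
                       visit_rate_later = 3,
                       followup_years = 7.5,
                       missingness = c(das = 0, pga = 0.25, cmas = 0.26,
                                       gc_dose = 0.55),
                       informative_missingness = FALSE,
                       cyc_duration_meanlog = log(5.2),
                       cyc_duration_sdlog = 0.2565,
                       cyc_duration_range = c(3, 9),
                       severity_sd_patient = 0.7,
                       severity_sd_visit = 0.6,
                       severity_ar = 0.85,
                       score_anchors = c(das = 3.2, pga = 5.2, cmas = 28),
                       score_noise = c(das = 0.4, pga = 0.8, cmas = 3),
                       seed = 20180325) {
  if (n_patients < 2) stopf("n_patients must be >= 2")
  if (frac_treated_target <= 0 || frac_treated_target >= 1)
    stopf("frac_treated_target must be in (0, 1)")
  if (any(missingness < 0 | missingness > 1))
    stopf("missingness probabilities must be in [0, 1]")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed %% .Machine$integer.max)
  class(cfg) <- "sim_config"
  cfg$init_intercept <- calibrate_init_intercept(cfg)
  cfg
}

# Visit schedule for one patient: first visit shortly after diagnosis, then
# gamma renewal intervals, denser in year 1.
draw_visit_times <- function(cfg, followup) {
  t <- stats::runif(1, 0, 0.5)
  times <- t
  repeat {
    mean_gap <- if (t < 12) 12 / cfg$visit_rate_year1 else 12 / cfg$visit_rate_later
    t <- t + stats::rgamma(1, shape = 4, scale = mean_gap / 4)
    if (t > followup) break
    times <- c(times, t)
  }
  times
}

# Latent severity path at given visit times: patient set point mu plus a
# mean-reverting (AR in continuous time) deviation.
draw_severity <- function(cfg, mu, times) {
  k <- length(times)
  dev <- numeric(k)
  dev[1] <- stats::rnorm(1, 0, cfg$severity_sd_visit)
  if (k > 1) for (j in 2:k) {
    rho <- cfg$severity_ar ^ (times[j] - times[j - 1])
    dev[j] <- rho * dev[j - 1] +
      stats::rnorm(1, 0, cfg$severity_sd_visit * sqrt(1 - rho^2))
  }
  mu + dev
}

# Deterministic calibration of the initiation-hazard intercept: solves for
# the expected ever-treated fraction over a fixed bank of latent paths.
calibrate_init_intercept <- function(cfg, n_paths = 1500) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(999983L)
  paths <- vector("list", n_paths)
  for (i in seq_len(n_paths)) {
    fu <- stats::runif(1, 24, 2 * 12 * cfg$followup_years - 24)
    times <- draw_visit_times(cfg, fu)
    mu <- stats::rnorm(1, 0, cfg$severity_sd_patient)
    s <- draw_severity(cfg, mu, times)
    paths[[i]] <- cbind(times, s, stats::rnorm(length(times)))
  }
  # the hazard acts on the recorded score composite = latent severity plus
  # weighted measurement noise (weights 0.5/0.25/0.25)
  noise_sd <- sqrt((0.5 * cfg$score_noise[["das"]] / 0.8)^2 +
                     (0.25 * cfg$score_noise[["pga"]] / 1.8)^2 +
                     (0.25 * cfg$score_noise[["cmas"]] / 9)^2)
  frac <- function(a) {
    p_ever <- vapply(paths, function(m) {
      p <- stats::plogis(a + cfg$confounding_strength *
                           (m[, 2] + m[, 3] * noise_sd) +
                           cfg$init_time_decay * m[, 1])
      1 - prod(1 - p)
    }, numeric(1))
    mean(p_ever) - cfg$frac_treated_target
  }
  stats::uniroot(frac, c(-12, 4), tol = 1e-4)$root
}

#' Simulate a synthetic juvenile dermatomyositis cohort
#'
#' Generates a cohort with the statistical structure the analysis assumes:
#' each patient carries a latent severity set point; severity evolves as a
#' mean-reverting process; observed DAS/PGA/CMAS are monotone noisy affine
#' transforms of severity clipped to their clinical ranges (CMAS is
#' reverse-coded: lower = worse); at each visit an untreated patient
#' initiates cyclophosphamide with probability logistic in the recorded
#' severity -- the composite of the chart scores the treating clinician
#' actually sees -- and time since diagnosis (confounding by indication,
#' fully captured by recorded covariates); course length is
#' lognormal, truncated; after initiation the observed scores receive the
#' planted additive treatment-recency effects, and item missingness is
#' applied (the registry can lose a score the clinician saw, so the
#' indication composite uses all three chart values, weighted towards the
#' always-recorded skin score).  Concomitant-medication flags and
#' ever-recorded clinical features are correlated with the severity set
#' point.
#'
#' @param config a [sim_config()].
#' @return a list of class `cyc_simulation` with elements `cohort` (a
#'   `cohort_table`), and `truth` (config echo, per-visit latent severity
#'   paths, planted effects, the calibrated initiation intercept, and a
#'   `positivity_warning` flag set when any initiation probability is
#'   numerically 0 or 1).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_patients
  mu <- stats::rnorm(n, 0, cfg$severity_sd_patient)
  sex <- ifelse(stats::runif(n) < 0.66, "female", "male")
  age <- round(clip(stats::rnorm(n, 8, 3.5) - 0.8 * mu, 1.5, 16.5), 1)
  followup <- stats::runif(n, 24, 2 * 12 * cfg$followup_years - 24)

  med_p <- cbind(
    oral_gc = stats::plogis(2.2 + 0.4 * mu),
    iv_gc = stats::plogis(-0.3 + 0.8 * mu),
    mtx = stats::plogis(2.5 + 0.3 * mu),
    ivig = stats::plogis(-1.8 + 0.8 * mu),
    hcq = stats::plogis(-1.3 + 0.4 * mu),
    aza = stats::plogis(-1.9 + 0.3 * mu),
    mmf = stats::plogis(-2.7 + 0.3 * mu),
    biologic = stats::plogis(-2.0 + 0.7 * mu))
  med_flags <- matrix(stats::runif(n * ncol(med_p)) < med_p, nrow = n,
                      dimnames = list(NULL, colnames(med_p)))
  feat_p <- cbind(
    calcinosis = stats::plogis(-1.3 + 0.6 * mu),
    ulceration = stats::plogis(-1.6 + 0.8 * mu),
    lipoatrophy = stats::plogis(-1.8 + 0.5 * mu),
    abnormal_respiration = stats::plogis(-1.7 + 0.7 * mu),
    edema = stats::plogis(0.1 + 0.6 * mu))
  feats <- matrix(stats::runif(n * ncol(feat_p)) < feat_p, nrow = n,
                  dimnames = list(NULL, colnames(feat_p)))

  pid <- sprintf("P%04d", seq_len(n))
  positivity_warning <- FALSE
  vis <- vector("list", n)
  lat <- vector("list", n)
  cyc_start <- rep(NA_real_, n)
  cyc_stop <- rep(NA_real_, n)

  eff <- function(v) c(0, unname(v))  # indexed by split-time level

  for (i in seq_len(n)) {
    times <- round(draw_visit_times(cfg, followup[i]), 3)
    times <- times[!duplicated(times)]
    s <- draw_severity(cfg, mu[i], times)
    k <- length(times)
    e_das <- stats::rnorm(k, 0, cfg$score_noise[["das"]])
    e_pga <- stats::rnorm(k, 0, cfg$score_noise[["pga"]])
    e_cmas <- stats::rnorm(k, 0, cfg$score_noise[["cmas"]])
    # recorded scores as they stand before any treatment effect; the
    # treating clinician acts on these chart values
    u_das <- clip(cfg$score_anchors[["das"]] + 0.8 * s + e_das, 0, 5)
    u_pga <- clip(cfg$score_anchors[["pga"]] + 1.8 * s + e_pga, 0, 10)
    u_cmas <- clip(cfg$score_anchors[["cmas"]] - 9 * s + e_cmas, 0, 52)
    # item missingness is decided per visit; the registry may lose a score
    # the clinician recorded on paper, so the indication composite below
    # still uses all three chart values
    tilt <- function(rate) {
      if (is.na(rate) || rate == 0) return(rep(FALSE, k))
      pr <- if (cfg$informative_missingness)
        stats::plogis(stats::qlogis(clip(rate, 1e-6, 1 - 1e-6)) + 0.5 * s)
      else rep(rate, k)
      stats::runif(k) < pr
    }
    mis_pga <- tilt(cfg$missingness[["pga"]])
    mis_cmas <- tilt(cfg$missingness[["cmas"]])
    # skin-dominant indication: ulcerative skin disease is the leading
    # clinical indication for cyclophosphamide, and the skin score is
    # assessed at every visit
    sev_obs <- 0.5 * (u_das - cfg$score_anchors[["das"]]) / 0.8 +
      0.25 * (u_pga - cfg$score_anchors[["pga"]]) / 1.8 +
      0.25 * (cfg$score_anchors[["cmas"]] - u_cmas) / 9
    # severity-driven initiation on the recorded composite, single course
    lp <- cfg$init_intercept + cfg$confounding_strength * sev_obs +
      cfg$init_time_decay * times
    p_init <- stats::plogis(lp)
    if (any(p_init <= 0 | p_init >= 1)) positivity_warning <- TRUE
    u <- stats::runif(k)
    start_j <- NA_integer_
    for (j in seq_len(k)) {
      if (u[j] < p_init[j]) { start_j <- j; break }
    }
    if (!is.na(start_j)) {
      cyc_start[i] <- times[start_j]
      d <- exp(stats::rnorm(1, cfg$cyc_duration_meanlog, cfg$cyc_duration_sdlog))
      d <- clip(d, cfg$cyc_duration_range[1], cfg$cyc_duration_range[2])
      cyc_stop[i] <- round(cyc_start[i] + d, 3)
    }
    st <- as.integer(split_time(times, cyc_start[i]))
    das <- clip(cfg$score_anchors[["das"]] + 0.8 * s + eff(cfg$effect_das)[st] +
                  e_das, 0, 5)
    pga <- clip(cfg$score_anchors[["pga"]] + 1.8 * s + eff(cfg$effect_pga)[st] +
                  e_pga, 0, 10)
    cmas <- clip(cfg$score_anchors[["cmas"]] - 9 * s + eff(cfg$effect_cmas)[st] +
                   e_cmas, 0, 52)
    pga[mis_pga] <- NA_real_
    cmas[mis_cmas] <- NA_real_
    gc <- if (med_flags[i, "oral_gc"]) {
      pmax(0, (12 + 5 * s) * exp(-0.05 * times) + stats::rnorm(k, 0, 2))
    } else rep(0, k)
    vis[[i]] <- data.frame(
      patient_id = pid[i], t_months = round(times, 3),
      das = round(das, 1), pga = round(pga, 1), cmas = round(cmas, 1),
      gc_dose_mg_day = round(gc, 1),
      on_cyc = !is.na(cyc_start[i]) & times >= cyc_start[i] &
        times < cyc_stop[i],
      stringsAsFactors = FALSE)
    for (m in colnames(med_flags)) vis[[i]][[m]] <- med_flags[i, m]
    lat[[i]] <- data.frame(patient_id = pid[i], t_months = times,
                           severity = s, sev_obs = sev_obs, p_init = p_init)
  }

  patients <- data.frame(
    patient_id = pid, sex = sex, age_at_diagnosis_years = age,
    cyc_start_months = round(cyc_start, 3), cyc_stop_months = round(cyc_stop, 3),
    stringsAsFactors = FALSE)
  for (f in colnames(feats)) patients[[f]] <- feats[, f]

  cohort <- cohort_table(patients, do.call(rbind, vis))
  # glucocorticoid-dose missingness plays no role in treatment decisions
  # and is planted after the fact; pga/cmas cells were masked in the loop
  gcr <- if ("gc_dose" %in% names(cfg$missingness))
    cfg$missingness[["gc_dose"]] else 0
  gc_rates <- c(das = 0, pga = 0, cmas = 0, gc_dose = gcr)
  cohort <- plant_missingness(cohort, gc_rates,
                              seed = derive_seed(cfg$seed, 104729L),
                              severity = if (cfg$informative_missingness)
                                do.call(rbind, lat)$severity)
  truth <- list(config = cfg, latent = do.call(rbind, lat),
                planted_effects = list(das = cfg$effect_das,
                                       pga = cfg$effect_pga,
                                       cmas = cfg$effect_cmas),
                init_intercept = cfg$init_intercept,
                positivity_warning = positivity_warning)
  structure(list(cohort = cohort, truth = truth), class = "cyc_simulation")
}

#' @export
print.cyc_simulation <- function(x, ...) {
  cat("synthetic cohort simulation\n")
  print(x$cohort)
  cat(sprintf("  calibrated initiation intercept: %.3f; positivity warning: %s\n",
              x$truth$init_intercept, x$truth$positivity_warning))
  invisible(x)
}

#' Plant item missingness in a cohort
#'
#' Independently sets each score missing with the given per-score
#' probability.  The skin score DAS is never made missing (its registry
#' missingness is 0% at every analysed time point); requesting a positive
#' DAS rate is a validation error.  The input cohort is not modified.
#'
#' @param cohort a `cohort_table`.
#' @param rates named probabilities for `das`, `pga`, `cmas`, `gc_dose`.
#' @param seed integer seed.
#' @param severity optional per-visit latent severity; when supplied, the
#'   missingness probability is tilted upwards with severity (logit shift of
#'   0.5 per severity unit), for sensitivity experiments.
#' @return a new `cohort_table` with missing cells planted.
#' @export
plant_missingness <- function(cohort, rates, seed = 1L, severity = NULL) {
  if (any(rates < 0 | rates > 1)) stopf("missingness rates must be in [0, 1]")
  if (!is.na(rates["das"]) && rates[["das"]] > 0)
    stopf("DAS cannot be made missing (registry DAS missingness is 0%%)")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  v <- cohort$visits
  k <- nrow(v)
  pr <- function(rate) {
    if (is.null(severity)) rep(rate, k)
    else stats::plogis(stats::qlogis(clip(rate, 1e-6, 1 - 1e-6)) +
                         0.5 * severity)
  }
  for (var in c("pga", "cmas", "gc_dose")) {
    rate <- rates[[var]] %||% 0
    if (is.na(rate) || rate == 0) next
    col <- if (var == "gc_dose") "gc_dose_mg_day" else var
    v[[col]][stats::runif(k) < pr(rate)] <- NA_real_
  }
  cohort_table(cohort$patients, v)
}

#' Run a pipeline over independent simulated replicate cohorts
#'
#' Generates `n_reps` independent cohorts (replicate seeds derived
#' deterministically from the configuration's master seed) and applies a
#' callback to each.  A failing replicate is recorded and the run
#' continues.
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicates (>= 1).
#' @param fn callback `function(cohort, truth)`; its return values are
#'   collected.
#' @return list with `results` (per-replicate callback outputs; `NULL` where
#'   a replicate failed), `errors` (condition messages by replicate index),
#'   and `seeds`.
#' @export
simulate_replicates <- function(config, n_reps, fn) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  seeds <- vapply(seq_len(n_reps), function(i) derive_seed(config$seed, i),
                  integer(1))
  results <- vector("list", n_reps)
  errors <- list()
  for (i in seq_len(n_reps)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    sim <- simulate_cohort(cfg_i)
    results[[i]] <- tryCatch(fn(sim$cohort, sim$truth), error = function(e) {
      errors[[as.character(i)]] <<- conditionMessage(e)
      NULL
    })
  }
  list(results = results, errors = errors, seeds = seeds)
}
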