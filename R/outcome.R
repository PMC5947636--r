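#' Weighted longitudinal outcome model
#'
#' Final analytical model of the pipeline: an identity-link estimating
#' equation fit (independence working correlation) of a disease-activity
#' score on time since diagnosis and the treatment-recency ("split time")
#' categorical covariate, weighted by truncated stabilized inverse
#' probability-of-treatment weights, with cluster-by-patient robust
#' (sandwich) variance that incorporates the weights.  With all weights
#' equal to 1 and one visit per patient this reduces exactly to ordinary
#' least squares.  The reference category is never/not-yet treated, so the
#' three reported coefficients are the average score differences for
#' courses started within 6 months, 6-12 months, and more than 12 months
#' ago, relative to never/not-yet-treated patient-visits.
#'
#' @param cohort a completed (imputed) `cohort_table`; the outcome must be
#'   complete.
#' @param weights a `weight_series` aligned to the cohort's visits (a
#'   `weight` column is used if present, else `raw_weight`); `NULL` fits
#'   the unweighted comparator.
#' @param outcome `"das"`, `"pga"` or `"cmas"`.
#' @param level confidence level for Wald intervals (default 0.95).
#' @param vcov_type cluster-sandwich flavour passed to
#'   [sandwich::vcovCL()]: `"HC1"` (default; calibrated for the
#'   cross-fitted weighting pipeline, where the robust variance is already
#'   conservative because weight estimation is ignored) or the
#'   bias-reduced `"HC2"`/`"HC3"` forms, appropriate with in-sample
#'   weights whose plain sandwich understates sampling variability.
#' @return an object of class `outcome_fit`: list with `estimates` (data
#'   frame of term, estimate, robust_se, ci_low, ci_high, p_value,
#'   estimable), `outcome`, `n_patients`, `n_visits`, `rank`.
#' @export
fit_weighted_outcome <- function(cohort, weights = NULL,
                                 outcome = c("das", "pga", "cmas"),
                                 level = 0.95,
                                 vcov_type = c("HC1", "HC2", "HC3")) {
  outcome <- match.arg(outcome)
  vcov_type <- match.arg(vcov_type)
  v <- visit_frame(cohort)
  if (!is.null(weights)) {
    key_v <- paste(v$patient_id, v$t_months)
    key_w <- paste(weights$patient_id, weights$t_months)
    w <- (weights$weight %||% weights$raw_weight)[match(key_v, key_w)]
    if (anyNA(w)) stopf("weights not aligned to cohort visits")
  } else {
    w <- rep(1, nrow(v))
  }
  ok <- !is.na(v[[outcome]])
  v <- v[ok, , drop = FALSE]; w <- w[ok]
  if (nrow(v) == 0) stopf("no non-missing %s values", outcome)

  full_terms <- c("t_months", paste0("st", split_time_levels[-1]))
  observed <- split_time_levels[split_time_levels %in% unique(as.character(v$st))]
  v$st <- factor(as.character(v$st), levels = observed)
  form <- stats::as.formula(paste(outcome, "~ t_months",
                                  if (length(observed) > 1) "+ st" else ""))
  dat <- v; dat$.w <- w
  fit <- stats::lm(form, data = dat, weights = .w)
  # fall back to HC1 when a cluster's leverage makes the bias-reduced
  # adjustments singular (tiny cohorts)
  V <- tryCatch(
    sandwich::vcovCL(fit, cluster = dat$patient_id, type = vcov_type),
    error = function(e)
      sandwich::vcovCL(fit, cluster = dat$patient_id, type = "HC1"))
  est <- stats::coef(fit)
  se <- sqrt(diag(V))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tab <- data.frame(term = names(est), estimate = unname(est),
                    robust_se = unname(se),
                    ci_low = unname(est - z * se),
                    ci_high = unname(est + z * se),
                    p_value = 2 * stats::pnorm(-abs(unname(est / se))),
                    estimable = TRUE, row.names = NULL,
                    stringsAsFactors = FALSE)
  # categories with no observed visits are reported as inestimable
  missing_terms <- setdiff(full_terms, tab$term)
  missing_terms <- missing_terms[missing_terms != "t_months"]
  if (length(missing_terms) > 0)
    tab <- rbind(tab, data.frame(term = missing_terms, estimate = NA_real_,
                                 robust_se = NA_real_, ci_low = NA_real_,
                                 ci_high = NA_real_, p_value = NA_real_,
                                 estimable = FALSE))
  structure(list(estimates = tab, outcome = outcome,
                 n_patients = length(unique(v$patient_id)),
                 n_visits = nrow(v), rank = fit$rank,
                 object = list(coef_table = tab)),
            class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(sprintf("outcome_fit [%s]: %d visits, %d patients\n", x$outcome,
              x$n_visits, x$n_patients))
  print(x$estimates, digits = 3)
  invisible(x)
}

#' Pool estimates across imputed sets by Rubin's rules
#'
#' Combines one coefficient's estimates from `m` imputed-set fits: pooled
#' point estimate = mean; within-imputation variance `W` = mean squared
#' standard error; between-imputation variance `B` = sample variance of
#' the estimates; total variance `T = W + (1 + 1/m) B`.  Confidence
#' intervals and p-values use a t reference with Barnard-Rubin
#' small-sample degrees of freedom (complete-data df taken as
#' `n_patients - rank`).
#'
#' @param fits list of `m >= 2` `outcome_fit` objects for the same outcome
#'   (one per imputed set), with identical term sets.
#' @param level confidence level (default 0.95).
#' @return data frame of class `pooled_effect`: one row per term with
#'   `estimate`, `W`, `B`, `T`, `se`, `df`, `ci_low`, `ci_high`,
#'   `p_value`, `m`, `estimable`.
#' @export
pool_rubin <- function(fits, level = 0.95) {
  m <- length(fits)
  if (m < 2) stopf("need m >= 2 imputed-set fits to pool")
  terms <- fits[[1]]$estimates$term
  for (f in fits)
    if (!identical(sort(f$estimates$term), sort(terms)))
      stopf("mismatched coefficient sets across imputed sets")
  nu_com <- max(fits[[1]]$n_patients - fits[[1]]$rank, 1)
  out <- NULL
  for (tm in terms) {
    q <- vapply(fits, function(f)
      f$estimates$estimate[f$estimates$term == tm], numeric(1))
    u <- vapply(fits, function(f)
      f$estimates$robust_se[f$estimates$term == tm]^2, numeric(1))
    if (anyNA(q)) {
      out <- rbind(out, data.frame(
        term = tm, estimate = NA_real_, W = NA_real_, B = NA_real_,
        T = NA_real_, se = NA_real_, df = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p_value = NA_real_, m = m, estimable = FALSE))
      next
    }
    qbar <- mean(q)
    W <- mean(u)
    B <- stats::var(q)
    Tv <- W + (1 + 1 / m) * B
    se <- sqrt(Tv)
    lam <- (1 + 1 / m) * B / Tv
    if (lam < .Machine$double.eps) {
      df <- nu_com
    } else {
      df_old <- (m - 1) / lam^2
      df_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lam)
      df <- 1 / (1 / df_old + 1 / df_obs)
    }
    tq <- stats::qt(1 - (1 - level) / 2, df)
    out <- rbind(out, data.frame(
      term = tm, estimate = qbar, W = W, B = B, T = Tv, se = se, df = df,
      ci_low = qbar - tq * se, ci_high = qbar + tq * se,
      p_value = 2 * stats::pt(-abs(qbar / se), df), m = m,
      estimable = TRUE))
  }
  rownames(out) <- NULL
  class(out) <- c("pooled_effect", "data.frame")
  out
}

#' Run the full marginal structural model pipeline
#'
#' Orchestrates the whole analysis on one cohort: eligibility filtering,
#' multiple imputation of missing PGA/CMAS (`m` sets), then per imputed
#' set the three-part probability-of-treatment model (denominator and
#' baseline-covariate stabilizer), stabilized truncated inverse
#' probability-of-treatment weights, and the weighted outcome model per
#' requested outcome; finally Rubin pooling across sets.
#'
#' @param cohort a `cohort_table`.
#' @param outcomes outcomes to model (default all three scores).
#' @param m number of imputed sets (default 5).
#' @param seed master seed for the imputation draws.
#' @param cap weight truncation point (default 20).
#' @param stabilized use stabilized weights (default `TRUE`).
#' @param control a [potm_control()].
#' @param also_unweighted additionally fit the unweighted comparator
#'   models (for confounding diagnostics).
#' @param eligibility apply [apply_eligibility()] first (default `TRUE`).
#' @param crossfit_folds patient folds for cross-fitted denominator
#'   probabilities (see [crossfit_treatment_probabilities()]); 0 uses
#'   in-sample predictions.
#' @param potm_missing_indicators add missing-indicator terms (imputed-cell
#'   flags and score-by-flag interactions) to the denominator
#'   probability-of-treatment sub-models; off by default — in calibration
#'   runs the extra parameters cost more than the errors-in-variables
#'   correction gained.
#' @param imputation_treatment_predictor treatment-status predictor passed
#'   to [impute_cohort()] (`"split_time"` keeps the imputation model
#'   congenial with the analysis model).
#' @return object of class `msm_result`: list with `pooled` (named list of
#'   `pooled_effect` per outcome), `per_set` (per-set estimate data frame),
#'   `weights_summary`, `unweighted` (when requested), `exclusions`, `m`,
#'   `cap`, `stabilized`.
#' @export
run_msm <- function(cohort, outcomes = c("das", "pga", "cmas"), m = 5,
                    seed = 1L, cap = 20, stabilized = TRUE,
                    control = potm_control(), also_unweighted = FALSE,
                    eligibility = TRUE, crossfit_folds = 5,
                    potm_missing_indicators = FALSE,
                    imputation_treatment_predictor = "split_time") {
  outcomes <- match.arg(outcomes, c("das", "pga", "cmas"), several.ok = TRUE)
  exclusions <- NULL
  if (eligibility) {
    cohort <- apply_eligibility(cohort)
    exclusions <- attr(cohort, "exclusions")
  }
  sets <- impute_cohort(cohort, m = m, seed = seed,
                        treatment_predictor = imputation_treatment_predictor)
  wsum <- NULL
  fits_by_outcome <- stats::setNames(
    replicate(length(outcomes), vector("list", m), simplify = FALSE),
    outcomes)
  unw_by_outcome <- if (also_unweighted) fits_by_outcome else NULL
  nobody_treated <- all(is.na(cohort$patients$cyc_start_months))
  for (k in seq_len(m)) {
    ck <- sets[[k]]$cohort
    if (potm_missing_indicators)
      for (sc in colnames(sets[[k]]$mask))
        ck$visits[[paste0(sc, "_imputed")]] <- sets[[k]]$mask[, sc]
    if (nobody_treated) {
      # no treatment decisions to model: weights are trivially 1 and the
      # split-time contrasts will be reported as inestimable
      ws <- data.frame(patient_id = ck$visits$patient_id,
                       t_months = ck$visits$t_months, raw_weight = 1)
      class(ws) <- c("weight_series", "data.frame")
    } else {
      dp <- if (crossfit_folds > 0) {
        crossfit_treatment_probabilities(ck, control, folds = crossfit_folds,
                                         seed = derive_seed(seed, 500L + k))
      } else {
        predict_treatment_probabilities(fit_potm(ck, control,
                                                 numerator = FALSE), ck)
      }
      if (stabilized) {
        num <- fit_potm(ck, control, numerator = TRUE)
        np <- predict_treatment_probabilities(num, ck)
        ws <- compute_weights(dp, np)
      } else {
        ws <- compute_weights(dp)
      }
    }
    ws <- truncate_weights(ws, cap)
    s <- summary(ws)
    wsum <- rbind(wsum, data.frame(set = k, t(s)))
    for (oc in outcomes) {
      fits_by_outcome[[oc]][[k]] <- fit_weighted_outcome(ck, ws, oc)
      if (also_unweighted)
        unw_by_outcome[[oc]][[k]] <- fit_weighted_outcome(ck, NULL, oc)
    }
  }
  pooled <- lapply(fits_by_outcome, pool_rubin)
  per_set <- do.call(rbind, lapply(outcomes, function(oc) {
    do.call(rbind, lapply(seq_len(m), function(k) {
      e <- fits_by_outcome[[oc]][[k]]$estimates
      cbind(outcome = oc, set = k, e)
    }))
  }))
  out <- list(pooled = pooled,
              unweighted = if (also_unweighted)
                lapply(unw_by_outcome, pool_rubin),
              per_set = per_set, weights_summary = wsum,
              exclusions = exclusions, m = m, cap = cap,
              stabilized = stabilized, outcomes = outcomes)
  class(out) <- "msm_result"
  out
}

#' @export
print.msm_result <- function(x, ...) {
  cat(sprintf("msm_result: %d imputed sets, weights %s (cap %g)\n", x$m,
              if (x$stabilized) "stabilized" else "unstabilized", x$cap))
  print(forest_table(x), digits = 3)
  invisible(x)
}

#' Tabular forest report of the pooled treatment-recency effects
#'
#' One row per outcome x treatment-recency category, ordered within
#' outcome as: within 6 months, 6-12 months, more than 12 months ago, with
#' pooled coefficient, 95% CI, p-value and a significance marker.
#' Inestimable entries (category unobserved) are reported as dashes.
#'
#' @param result an `msm_result` (or a named list of `pooled_effect`).
#' @param alpha significance marker level (default 0.05).
#' @return data frame with columns `outcome`, `category`, `coef`, `ci_low`,
#'   `ci_high`, `p_value`, `signif`.
#' @export
forest_table <- function(result, alpha = 0.05) {
  pooled <- if (inherits(result, "msm_result")) result$pooled else result
  cats <- paste0("st", split_time_levels[-1])
  labels <- c("CYC within last 6 months", "CYC 6-12 months ago",
              "CYC >12 months ago")
  out <- NULL
  for (oc in names(pooled)) {
    pe <- pooled[[oc]]
    for (j in seq_along(cats)) {
      row <- pe[pe$term == cats[j], , drop = FALSE]
      if (nrow(row) == 0 || !row$estimable) {
        out <- rbind(out, data.frame(outcome = oc, category = labels[j],
                                     coef = NA_real_, ci_low = NA_real_,
                                     ci_high = NA_real_, p_value = NA_real_,
                                     signif = "-", stringsAsFactors = FALSE))
      } else {
        out <- rbind(out, data.frame(
          outcome = oc, category = labels[j], coef = row$estimate,
          ci_low = row$ci_low, ci_high = row$ci_high,
          p_value = row$p_value,
          signif = ifelse(row$p_value < alpha, "*", ""),
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}
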