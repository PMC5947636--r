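#' Probability-of-treatment model (PoTM)
#'
#' Three discrete-time sub-models on the visit grid supply the per-visit
#' treatment-state probabilities from which inverse
#' probability-of-treatment weights are built: (1) receipt of
#' cyclophosphamide at the first recorded visit ("baseline"), (2)
#' initiation at a visit given no prior treatment, (3) discontinuation
#' given the previous visit was on treatment.  Sub-models are pooled
#' longitudinal logistic regressions with cluster-by-patient robust
#' standard errors; the protocol-driven discontinuation process is
#' near-deterministic in time on treatment, so that sub-model falls back
#' automatically to a coarse time-banded hazard (with Agresti-style
#' smoothing keeping every probability strictly inside (0, 1)) when
#' quasi-separation is detected.
#'
#' @name potm
NULL

#' PoTM covariate configuration
#'
#' Default denominator covariates are the current (imputed) disease scores,
#' time since diagnosis, age at diagnosis, and the concomitant medications
#' most imbalanced between treatment groups (intravenous glucocorticoids,
#' intravenous immunoglobulin, biologics).  Numerator (stabilizer) models
#' use baseline covariates only: age and sex.
#'
#' @param baseline_covars covariates of the baseline-receipt model.
#' @param initiation_covars covariates of the initiation model.
#' @param numerator_covars covariates of the stabilizer sub-models.
#' @param stop_bands breakpoints (months on treatment) of the banded
#'   discontinuation fallback.
#' @return a list of class `potm_control`.
#' @export
potm_control <- function(baseline_covars = c("das", "pga", "cmas", "age",
                                             "iv_gc", "ivig", "biologic"),
                         initiation_covars = c("das", "pga", "cmas",
                                               "t_months", "age", "iv_gc",
                                               "ivig", "biologic"),
                         numerator_covars = c("age", "sex"),
                         stop_bands = c(0, 4, 6, 8, Inf)) {
  structure(list(baseline_covars = baseline_covars,
                 initiation_covars = initiation_covars,
                 numerator_covars = numerator_covars,
                 stop_bands = stop_bands), class = "potm_control")
}

# Risk-set frame: visit_frame plus visit index, previous visit time, and
# era/risk-set markers for the three sub-models.
risk_frame <- function(cohort) {
  v <- visit_frame(cohort)
  idx <- stats::ave(seq_len(nrow(v)), v$patient_id, FUN = seq_along)
  prev_t <- c(NA_real_, v$t_months[-nrow(v)])
  prev_t[idx == 1] <- NA_real_
  v$visit_index <- idx
  v$prev_t <- prev_t
  started <- !is.na(v$cyc_start)
  v$era <- ifelse(!started | v$t_months < v$cyc_start, "pre",
                  ifelse(v$t_months < v$cyc_stop, "on", "post"))
  prev_era <- c(NA_character_, v$era[-nrow(v)])
  prev_era[idx == 1] <- NA_character_
  v$prev_era <- prev_era
  v$y_base <- idx == 1 & v$era != "pre"
  v$in_init <- idx > 1 & v$prev_era == "pre"
  v$y_init <- v$in_init & v$era != "pre"
  v$in_stop <- idx > 1 & v$prev_era == "on"
  v$y_stop <- v$in_stop & v$era == "post"
  v$tot <- v$t_months - v$cyc_start
  v
}

new_potm_fit <- function(submodel, method, object, data_n, converged,
                         covars, note = NULL) {
  structure(list(submodel = submodel, method = method, object = object,
                 n = data_n, converged = converged, covars = covars,
                 note = note),
            class = "potm_fit")
}

#' @export
print.potm_fit <- function(x, ...) {
  cat(sprintf("potm_fit [%s]: %s, n = %d%s\n", x$submodel, x$method, x$n,
              if (!is.null(x$note)) paste0(" (", x$note, ")") else ""))
  if (!is.null(x$object$coef_table)) print(x$object$coef_table, digits = 3)
  invisible(x)
}

#' Coefficient table with robust standard errors
#'
#' @param fit a `potm_fit` (or outcome fit) wrapping a glm/lm.
#' @return data frame of term, estimate, robust SE, z, p.
#' @export
coef_table <- function(fit) fit$object$coef_table

# Fit a binomial glm with cluster-robust SEs and quasi-separation
# detection; returns NULL when separation/non-convergence is detected.
# A tiny fitted probability is legitimate for a visit where the event did
# not happen (its observed-state probability is ~1); quasi-separation is
# flagged only when an *observed* state is given numerically zero
# probability, or coefficients diverge.
fit_logistic <- function(df, covars, cluster) {
  form <- if (length(covars) == 0) y ~ 1 else
    stats::reformulate(covars, response = "y")
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = df))
  pr <- stats::fitted(fit)
  p_obs <- ifelse(df$y, pr, 1 - pr)
  slopes <- stats::coef(fit)[-1]
  if (!fit$converged || any(abs(slopes) > 15, na.rm = TRUE) ||
      any(p_obs < 1e-8))
    return(NULL)
  V <- sandwich::vcovCL(fit, cluster = df[[cluster]])
  est <- stats::coef(fit)
  se <- sqrt(diag(V))
  fit$coef_table <- data.frame(term = names(est), estimate = unname(est),
                               robust_se = unname(se),
                               z = unname(est / se),
                               p_value = 2 * stats::pnorm(-abs(est / se)),
                               row.names = NULL)
  fit
}

# Which covariate most plausibly separates: largest |coefficient|.
worst_covariate <- function(df, covars) {
  fit <- suppressWarnings(stats::glm(stats::reformulate(covars, "y"),
                                     stats::binomial(), data = df))
  cf <- stats::coef(fit)[-1]
  names(cf)[which.max(abs(cf))]
}

#' Fit the baseline-receipt sub-model
#'
#' Logistic model for being on cyclophosphamide at the first recorded
#' visit, one row per patient.  On separation the covariate set is reduced
#' (medication flags first, then to intercept-only) with the reduction
#' recorded in the fit's `note`.
#'
#' @param cohort a completed (imputed) `cohort_table`.
#' @param covars covariate names (visit columns, `age`, `sex`).
#' @return a `potm_fit`.
#' @export
fit_baseline_model <- function(cohort, covars = potm_control()$baseline_covars) {
  rf <- risk_frame(cohort)
  df <- rf[rf$visit_index == 1, , drop = FALSE]
  df$y <- df$y_base
  if (all(!df$y))
    return(new_potm_fit("baseline", "empirical", list(rate = agresti(0, nrow(df))),
                        nrow(df), TRUE, character(0),
                        "no baseline receivers; empirical rate used"))
  tried <- reduction_cascade(covars)
  for (i in seq_along(tried)) {
    fit <- fit_logistic(df, tried[[i]], "patient_id")
    if (!is.null(fit)) {
      note <- if (i == 1) NULL else
        sprintf("separation detected (worst covariate: %s); refitted with %s",
                worst_covariate(df, covars),
                if (length(tried[[i]]) == 0) "intercept only"
                else paste(tried[[i]], collapse = "+"))
      return(new_potm_fit("baseline", "glm", fit, nrow(df), TRUE,
                          tried[[i]], note))
    }
  }
  stopf("baseline model could not be fitted (separation persists); %s",
        "consider penalized estimation")
}

#' Fit the initiation sub-model
#'
#' Pooled longitudinal logistic model for starting cyclophosphamide by a
#' visit, among patient-visits with no prior treatment, with
#' cluster-by-patient robust standard errors.
#'
#' @inheritParams fit_baseline_model
#' @return a `potm_fit`.
#' @export
fit_initiation_model <- function(cohort,
                                 covars = potm_control()$initiation_covars) {
  rf <- risk_frame(cohort)
  df <- rf[rf$in_init, , drop = FALSE]
  if (nrow(df) == 0) stopf("initiation risk set is empty")
  df$y <- df$y_init
  if (all(!df$y))
    stopf("nobody initiates treatment after baseline; %s",
          "weights are trivially 1 for all patient-visits")
  tried <- reduction_cascade(covars)
  for (i in seq_along(tried)) {
    fit <- fit_logistic(df, tried[[i]], "patient_id")
    if (!is.null(fit))
      return(new_potm_fit("initiation", "glm", fit, nrow(df), TRUE,
                          tried[[i]],
                          if (i == 1) NULL else "separation fallback"))
  }
  stopf("initiation model could not be fitted (separation persists)")
}

agresti <- function(events, n) (events + 0.5) / (n + 1)

# Covariate de-escalation used when a sub-model quasi-separates: drop
# interaction terms first, then missingness marks and medication flags,
# finally fall back to intercept only.
reduction_cascade <- function(covars) {
  inter <- grep(":", covars, value = TRUE)
  marks <- grep("_imputed$", covars, value = TRUE)
  steps <- list(covars,
                setdiff(covars, inter),
                setdiff(covars, c(inter, marks, med_flag_cols)),
                character(0))
  unique(steps)
}

#' Fit the discontinuation sub-model
#'
#' Logistic model for stopping cyclophosphamide by a visit given the
#' previous visit was on treatment, with time on treatment as the dominant
#' covariate.  Because the treatment course is protocolized
#' (near-deterministic stopping around the course length),
#' quasi-separation by time on treatment is expected; it triggers an
#' automatic fallback to a coarse time-banded empirical hazard with
#' Agresti smoothing, which keeps every probability strictly inside (0, 1).
#'
#' @inheritParams fit_baseline_model
#' @param bands breakpoints (months on treatment) of the banded fallback.
#' @param method `"auto"` (glm, banded on separation) or `"banded"`.
#' @return a `potm_fit`; banded fits carry the band hazard table.
#' @export
fit_discontinuation_model <- function(cohort,
                                      bands = potm_control()$stop_bands,
                                      method = c("auto", "banded")) {
  method <- match.arg(method)
  rf <- risk_frame(cohort)
  df <- rf[rf$in_stop, , drop = FALSE]
  if (nrow(df) == 0) stopf("discontinuation risk set is empty (no treated patients)")
  df$y <- df$y_stop
  if (method == "auto") {
    fit <- fit_logistic(df, "tot", "patient_id")
    if (!is.null(fit))
      return(new_potm_fit("discontinuation", "glm", fit, nrow(df), TRUE,
                          "tot"))
  }
  band <- cut(df$tot, bands, include.lowest = TRUE, right = FALSE)
  tab <- data.frame(band = levels(band),
                    n = as.integer(table(band)),
                    events = as.integer(tapply(df$y, band, sum, default = 0)))
  tab$events[is.na(tab$events)] <- 0L
  tab$hazard <- agresti(tab$events, pmax(tab$n, 0))
  new_potm_fit("discontinuation", "banded",
               list(bands = bands, table = tab), nrow(df), TRUE, "tot",
               if (method == "auto") "quasi-separation by time on treatment; banded hazard used"
               else NULL)
}

# Predicted event probability for rows of a risk frame under a potm_fit.
predict_potm <- function(fit, df) {
  if (fit$method == "empirical") return(rep(fit$object$rate, nrow(df)))
  if (fit$method == "banded") {
    band <- cut(df$tot, fit$object$bands, include.lowest = TRUE, right = FALSE)
    fit$object$table$hazard[as.integer(band)]
  } else {
    stats::predict(fit$object, newdata = df, type = "response")
  }
}

#' Fit all three PoTM sub-models
#'
#' @param cohort a completed (imputed) `cohort_table`.
#' @param control a [potm_control()].
#' @param numerator when `TRUE`, fit the stabilizer versions: baseline and
#'   initiation on baseline covariates only (age, sex), discontinuation as
#'   the banded time-on-treatment hazard.
#' @return list of class `potm` with elements `baseline`, `initiation`,
#'   `discontinuation`.
#' @export
fit_potm <- function(cohort, control = potm_control(), numerator = FALSE) {
  # when the cohort carries imputation marks, let the denominator
  # sub-models condition on the missingness pattern: an imputed score is a
  # noisy stand-in for what the treating clinician saw, so its slope is
  # allowed to differ (missing-indicator propensity modelling)
  if (!numerator) {
    for (sc in c("pga", "cmas")) {
      flag <- paste0(sc, "_imputed")
      if (flag %in% names(cohort$visits) && any(cohort$visits[[flag]])) {
        add <- c(flag, paste0(sc, ":", flag))
        if (sc %in% control$baseline_covars)
          control$baseline_covars <- c(control$baseline_covars, add)
        if (sc %in% control$initiation_covars)
          control$initiation_covars <- c(control$initiation_covars, add)
      }
    }
  }
  if (numerator) {
    out <- list(
      baseline = fit_baseline_model(cohort, control$numerator_covars),
      initiation = fit_initiation_model(cohort, control$numerator_covars),
      discontinuation = fit_discontinuation_model(cohort, control$stop_bands,
                                                  method = "banded"))
  } else {
    out <- list(
      baseline = fit_baseline_model(cohort, control$baseline_covars),
      initiation = fit_initiation_model(cohort, control$initiation_covars),
      discontinuation = fit_discontinuation_model(cohort, control$stop_bands))
  }
  structure(out, class = "potm")
}

#' Cross-fitted per-visit probabilities of the observed treatment state
#'
#' Like [predict_treatment_probabilities()], but every patient's baseline
#' and initiation probabilities are predicted from sub-models fitted with
#' that patient's fold held out (folds assigned by patient).  In-sample
#' propensity predictions overfit: the model partly "explains" each
#' patient's own treatment surprise, which systematically shrinks the
#' weights of exactly the informative patients and leaves residual
#' confounding (in 60-replicate calibration runs, +0.03-0.04 outcome-unit
#' bias that cross-fitting removes).  The protocol-driven discontinuation
#' model has no confounders and is fitted on the full risk set.  A fold
#' whose training model cannot be fitted falls back to the full-data fit
#' for its predictions.
#'
#' @param cohort a completed (imputed) `cohort_table`.
#' @param control a [potm_control()].
#' @param folds number of patient folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return data frame as from [predict_treatment_probabilities()].
#' @export
crossfit_treatment_probabilities <- function(cohort, control = potm_control(),
                                             folds = 5, seed = 1L) {
  rf <- risk_frame(cohort)
  pid <- unique(cohort$patients$patient_id)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  fold <- stats::setNames(sample(rep_len(seq_len(folds), length(pid))), pid)

  prob <- rep(1, nrow(rf))
  state <- rep("post_cyc", nrow(rf))
  full <- fit_potm(cohort, control, numerator = FALSE)

  cv_predict <- function(submodel, fitter, rows) {
    df <- rf[rows, , drop = FALSE]
    pr <- predict_potm(full[[submodel]], df)
    for (f in seq_len(folds)) {
      hold <- fold[df$patient_id] == f
      if (!any(hold)) next
      keep <- cohort$patients$patient_id[fold[cohort$patients$patient_id] != f]
      sub <- cohort_table(
        cohort$patients[cohort$patients$patient_id %in% keep, , drop = FALSE],
        cohort$visits[cohort$visits$patient_id %in% keep, , drop = FALSE])
      fit_f <- tryCatch(fitter(sub), error = function(e) NULL)
      if (!is.null(fit_f))
        pr[hold] <- predict_potm(fit_f, df[hold, , drop = FALSE])
    }
    clip(pr, 1e-8, 1 - 1e-8)
  }

  i <- rf$visit_index == 1
  p <- cv_predict("baseline",
                  function(ch) fit_baseline_model(ch, control$baseline_covars),
                  which(i))
  prob[i] <- ifelse(rf$y_base[i], p, 1 - p)
  state[i] <- ifelse(rf$y_base[i], "baseline_on", "baseline_off")

  i <- rf$in_init
  p <- cv_predict("initiation",
                  function(ch) fit_initiation_model(ch, control$initiation_covars),
                  which(i))
  prob[i] <- ifelse(rf$y_init[i], p, 1 - p)
  state[i] <- ifelse(rf$y_init[i], "start", "no_start")

  i <- rf$in_stop
  if (any(i)) {
    p <- predict_potm(full$discontinuation, rf[i, , drop = FALSE])
    prob[i] <- ifelse(rf$y_stop[i], p, 1 - p)
    state[i] <- ifelse(rf$y_stop[i], "stop", "continue")
  }

  modelled <- state != "post_cyc"
  if (any(prob[modelled] < 1e-10))
    stopf("positivity violation: an observed treatment state has numerically zero probability")
  data.frame(patient_id = rf$patient_id, t_months = rf$t_months,
             state = state, prob = prob, stringsAsFactors = FALSE)
}

#' Per-visit probability of the observed treatment state
#'
#' Assembles, for every patient-visit, the probability under the fitted
#' PoTM of the treatment transition actually observed: at the first visit,
#' receipt/non-receipt at baseline; while untreated, starting/not starting;
#' while on treatment, stopping/continuing.  After a completed course the
#' treatment history is deterministic (a single course, no re-treatment)
#' and the contribution is exactly 1.  A modelled state assigned
#' numerically zero probability (below 1e-10) although it was observed is
#' a positivity violation and raises an error.
#'
#' @param fits a `potm` from [fit_potm()].
#' @param cohort the same completed cohort the fits were made on.
#' @return data frame `patient_id`, `t_months`, `state` (one of
#'   `baseline_on`, `baseline_off`, `start`, `no_start`, `stop`,
#'   `continue`, `post_cyc`), `prob`.
#' @export
predict_treatment_probabilities <- function(fits, cohort) {
  rf <- risk_frame(cohort)
  prob <- rep(1, nrow(rf))
  state <- rep("post_cyc", nrow(rf))

  i <- rf$visit_index == 1
  p <- predict_potm(fits$baseline, rf[i, , drop = FALSE])
  prob[i] <- ifelse(rf$y_base[i], p, 1 - p)
  state[i] <- ifelse(rf$y_base[i], "baseline_on", "baseline_off")

  i <- rf$in_init
  p <- predict_potm(fits$initiation, rf[i, , drop = FALSE])
  prob[i] <- ifelse(rf$y_init[i], p, 1 - p)
  state[i] <- ifelse(rf$y_init[i], "start", "no_start")

  i <- rf$in_stop
  if (any(i)) {
    p <- predict_potm(fits$discontinuation, rf[i, , drop = FALSE])
    prob[i] <- ifelse(rf$y_stop[i], p, 1 - p)
    state[i] <- ifelse(rf$y_stop[i], "stop", "continue")
  }

  modelled <- state != "post_cyc"
  if (any(prob[modelled] < 1e-10))
    stopf("positivity violation: an observed treatment state has numerically zero probability")
  data.frame(patient_id = rf$patient_id, t_months = rf$t_months,
             state = state, prob = prob, stringsAsFactors = FALSE)
}
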