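#' Multiple imputation of missing PGA and CMAS scores
#'
#' Chained-equations imputation producing `m` stochastically completed
#' cohorts that are carried through the whole weighting pipeline and pooled
#' by Rubin's rules at the end.  Each incomplete variable is imputed from a
#' normal linear conditional model on the clinical predictors: the complete
#' skin score, the other incomplete score, time since diagnosis, the
#' treatment-recency (split-time) factor, and age at diagnosis, plus the
#' patient-level means of the score predictors, which carry each patient's
#' severity set point -- the longitudinal structure -- into the
#' conditionals.  Treatment status enters as the split-time factor rather
#' than a bare on-treatment flag so the imputation model is congenial with
#' the analysis model (an imputation model blind to a covariate of the
#' analysis model attenuates its effect).  Draws are "proper": for each
#' completion the regression parameters are drawn from their approximate
#' posterior (scaled inverse-chi-square for the residual variance, normal
#' for the coefficients) before residual noise is added, so that
#' between-imputation variance reflects estimation uncertainty.
#' Out-of-range draws are clipped to the score's clinical range.
#'
#' Glucocorticoid dose is not imputed by default: its missingness is both
#' heavy and plausibly informative, so analyses involving it are treated as
#' descriptive only.
#'
#' @param cohort a `cohort_table`; `das` must be complete.
#' @param m number of imputed sets (default 5).
#' @param seed integer seed; a fixed seed gives bit-identical sets.
#' @param vars variables to impute (subset of `"pga"`, `"cmas"`).
#' @param n_iter chained-equation sweeps per set (default 10).
#' @param treatment_predictor how treatment status enters the conditional
#'   models: the split-time recency factor (default; congenial with the
#'   analysis model) or a bare on-treatment flag.
#' @return a list of class `imputed_list` holding `m` objects of class
#'   `imputed_set`, each with elements `index`, `cohort` (completed), and
#'   `mask` (logical matrix of originally-missing cells).
#' @export
impute_cohort <- function(cohort, m = 5, seed = 1L,
                          vars = c("pga", "cmas"), n_iter = 10,
                          treatment_predictor = c("split_time", "on_cyc")) {
  treatment_predictor <- match.arg(treatment_predictor)
  v <- cohort$visits
  if (anyNA(v$das)) stopf("das must be complete prior to imputation")
  vars <- match.arg(vars, c("pga", "cmas"), several.ok = TRUE)
  mask <- sapply(vars, function(x) is.na(v[[x]]))
  if (!is.matrix(mask)) mask <- matrix(mask, ncol = length(vars),
                                       dimnames = list(NULL, vars))
  for (x in vars) if (all(mask[, x]))
    stopf("variable %s is missing for all rows; imputation model inestimable", x)
  p <- cohort$patients
  age <- p$age_at_diagnosis_years[match(v$patient_id, p$patient_id)]
  # congeniality: the imputation model must carry the analysis model's
  # covariates, so treatment status enters as the split-time factor
  if (treatment_predictor == "split_time") {
    st <- split_time(v$t_months,
                     p$cyc_start_months[match(v$patient_id, p$patient_id)])
    trt <- stats::model.matrix(~ st)[, -1, drop = FALSE]
  } else {
    trt <- cbind(on_cyc = as.numeric(v$on_cyc))
  }

  sets <- vector("list", m)
  for (k in seq_len(m)) {
    set.seed(derive_seed(seed, k))
    vv <- v
    if (any(mask)) {
      # initialise missing cells by sampling observed values
      for (x in vars) {
        obs <- vv[[x]][!mask[, x]]
        vv[[x]][mask[, x]] <- sample(obs, sum(mask[, x]), replace = TRUE)
      }
      for (it in seq_len(n_iter)) {
        for (x in vars) {
          if (!any(mask[, x])) next
          other <- setdiff(vars, x)
          # patient-level means carry the longitudinal structure (each
          # patient's severity set point) into the conditional model
          pm_das <- stats::ave(vv$das, vv$patient_id)
          X <- cbind(1, vv$das, vv$t_months, trt, age, pm_das)
          for (o in other)
            X <- cbind(X, vv[[o]], stats::ave(vv[[o]], vv$patient_id))
          vv[[x]][mask[, x]] <- draw_norm_imputation(
            y = v[[x]], X = X, miss = mask[, x],
            range = score_ranges[[x]])
        }
      }
      for (x in vars) vv[[x]] <- round(vv[[x]], 1)
      # originally-observed cells must be untouched
      for (x in vars) vv[[x]][!mask[, x]] <- v[[x]][!mask[, x]]
    }
    sets[[k]] <- structure(
      list(index = k, cohort = cohort_table(p, vv), mask = mask),
      class = "imputed_set")
  }
  structure(sets, class = "imputed_list")
}

# Bayesian linear-regression draw for the missing cells of y given design X
# (norm-style): sigma^2* ~ RSS/chisq, beta* ~ N(beta_hat, sigma^2* (X'X)^-1),
# y_mis* = X_mis beta* + sigma* eps, clipped to range.
draw_norm_imputation <- function(y, X, miss, range) {
  Xo <- X[!miss, , drop = FALSE]
  yo <- y[!miss]
  qrX <- qr(Xo)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[miss, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yo)
  p <- ncol(Xo); n <- length(yo)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / stats::rchisq(1, df = max(n - p, 1))
  XtX_inv <- chol2inv(chol(crossprod(Xo) + diag(1e-8, p)))
  beta <- fit$coefficients +
    drop(chol(sigma2 * XtX_inv) %*% stats::rnorm(p))
  draw <- drop(Xm %*% beta) + stats::rnorm(nrow(Xm), 0, sqrt(sigma2))
  clip(draw, range[1], range[2])
}

#' @export
print.imputed_list <- function(x, ...) {
  cat(sprintf("imputed_list: m = %d completed cohorts; %d originally-missing cells\n",
              length(x), sum(x[[1]]$mask)))
  invisible(x)
}

#' Apply a pipeline stage to every imputed set
#'
#' Runs a downstream stage independently on each completed cohort,
#' preserving set order so outputs stay aligned for pooling.  A failure on
#' any set aborts with the set index: pooling over a subset of imputations
#' would bias the Rubin variance.
#'
#' @param sets an `imputed_list` (or plain list of `imputed_set`).
#' @param fn callback `function(cohort, index)` or `function(cohort)`.
#' @return list of per-set outputs, in set order.
#' @export
across_sets <- function(sets, fn) {
  stopifnot(length(sets) >= 1)
  takes_index <- length(formals(fn)) >= 2
  lapply(seq_along(sets), function(k) {
    tryCatch({
      if (takes_index) fn(sets[[k]]$cohort, k) else fn(sets[[k]]$cohort)
    }, error = function(e) {
      stopf("stage failed on imputed set %d: %s", k, conditionMessage(e))
    })
  })
}

#' Write imputed sets to delimited files
#'
#' Each completed cohort is written in the interchange format with the set
#' index in the filenames.
#'
#' @param sets an `imputed_list`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return written paths, invisibly.
#' @export
write_imputed <- function(sets, dir, prefix = "imputed") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in sets) {
    vf <- file.path(dir, sprintf("%s_%d_visits.csv", prefix, s$index))
    pf <- file.path(dir, sprintf("%s_%d_patients.csv", prefix, s$index))
    write_cohort(s$cohort, vf, pf)
    paths <- c(paths, vf, pf)
  }
  invisible(paths)
}
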