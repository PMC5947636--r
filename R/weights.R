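#' Stabilized inverse probability-of-treatment weights
#'
#' The weight of a patient-visit is the cumulative product, over that
#' patient's visits up to and including the current one, of the ratio of
#' the stabilizer (numerator) probability of the observed treatment state
#' to its covariate-conditional (denominator) probability.  In the
#' re-weighted pseudo-population, confounders and treatment assignment are
#' unrelated, so the weighted outcome model estimates the causal treatment
#' effect.  Unstabilized weights set the numerator to 1 everywhere.
#'
#' @param den_probs denominator per-visit probabilities from
#'   [predict_treatment_probabilities()] (covariate-conditional PoTM).
#' @param num_probs optional numerator probabilities on the same visits
#'   (baseline-covariates-only PoTM).  `NULL` gives unstabilized weights.
#' @return a data frame of class `weight_series`: `patient_id`, `t_months`,
#'   `raw_weight`, with attribute `stabilized`.
#' @export
compute_weights <- function(den_probs, num_probs = NULL) {
  if (any(den_probs$prob == 0)) stopf("denominator probability of 0; cannot weight")
  if (!is.null(num_probs)) {
    if (nrow(num_probs) != nrow(den_probs) ||
        any(num_probs$patient_id != den_probs$patient_id) ||
        any(num_probs$t_months != den_probs$t_months))
      stopf("numerator/denominator risk-set mismatch")
    ratio <- num_probs$prob / den_probs$prob
  } else {
    ratio <- 1 / den_probs$prob
  }
  # cumulative product within patient, visits already in time order
  logr <- log(ratio)
  w <- exp(stats::ave(logr, den_probs$patient_id, FUN = cumsum))
  out <- data.frame(patient_id = den_probs$patient_id,
                    t_months = den_probs$t_months,
                    raw_weight = w, stringsAsFactors = FALSE)
  class(out) <- c("weight_series", "data.frame")
  attr(out, "stabilized") <- !is.null(num_probs)
  out
}

#' Truncate extreme weights
#'
#' Replaces every weight by `min(weight, cap)`.  Inverse
#' probability-of-treatment weights can be highly skewed, letting single
#' observations dominate the weighted fit; capping (conventionally at 20)
#' bounds that influence at the cost of some bias.  Monotone and
#' idempotent; the number of capped visits is recorded in attribute
#' `"n_truncated"`.
#'
#' @param weights a `weight_series`.
#' @param cap positive truncation point (default 20; `Inf` = identity).
#' @return the `weight_series` with a `weight` column of truncated weights.
#' @export
truncate_weights <- function(weights, cap = 20) {
  if (cap <= 0) stopf("cap must be positive")
  base <- if ("weight" %in% names(weights)) weights$weight else
    weights$raw_weight
  weights$weight <- pmin(base, cap)
  attr(weights, "cap") <- cap
  attr(weights, "n_truncated") <- sum(base > cap)
  weights
}

#' Summary of a weight series
#' @param object a `weight_series`.
#' @param ... ignored.
#' @export
summary.weight_series <- function(object, ...) {
  w <- object$raw_weight
  out <- c(n = length(w), mean_raw = mean(w), max_raw = max(w),
           p99_raw = unname(stats::quantile(w, 0.99)),
           n_truncated = attr(object, "n_truncated") %||% NA_integer_,
           cap = attr(object, "cap") %||% NA_real_)
  out
}

# Weighted mean and normal-approximation CI via the effective sample size.
wtd_mean_ci <- function(x, w, level = 0.95) {
  ok <- !is.na(x)
  x <- x[ok]; w <- w[ok]
  if (length(x) == 0) return(c(mean = NA, lo = NA, hi = NA, n = 0))
  m <- sum(w * x) / sum(w)
  ess <- sum(w)^2 / sum(w^2)
  v <- sum(w * (x - m)^2) / sum(w)
  se <- sqrt(v / max(ess - 1, 1))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(mean = m, lo = m - z * se, hi = m + z * se, n = length(x))
}

#' Covariate-balance diagnostics for the weighted pseudo-population
#'
#' Compares a disease-activity measure between the never/not-yet-treated
#' patient-visits and the treated-era patient-visits over a time grid
#' covering the first two years after diagnosis, before and after
#' weighting.  For each time bin it reports the unweighted and weighted
#' group means with normal-approximation confidence intervals (weighted
#' case via the effective sample size) and the standardized mean
#' difference.  Weighting a confounded cohort should shrink the
#' standardized differences.  Empty bins are flagged, not fabricated.
#'
#' @param cohort a `cohort_table` (completed scores for the chosen measure).
#' @param weights a truncated `weight_series` aligned to the cohort's
#'   visits.
#' @param measure `"das"`, `"pga"` or `"cmas"`.
#' @param breaks time-grid bin edges in months since diagnosis.
#' @param level confidence level.
#' @return data frame, one row per bin x group, with unweighted and
#'   weighted means/CIs, plus columns `std_diff_unweighted`,
#'   `std_diff_weighted` (repeated within bin) and `empty` flags.
#' @export
balance_diagnostics <- function(cohort, weights, measure = "das",
                                breaks = seq(0, 24, by = 3), level = 0.95) {
  v <- visit_frame(cohort)
  key_v <- paste(v$patient_id, v$t_months)
  key_w <- paste(weights$patient_id, weights$t_months)
  w <- (weights$weight %||% weights$raw_weight)[match(key_v, key_w)]
  if (anyNA(w)) stopf("weights not aligned to cohort visits")
  keep <- v$t_months <= max(breaks)
  v <- v[keep, , drop = FALSE]
  w <- w[keep]
  grp <- ifelse(v$st == "never_not_yet", "never_not_yet", "cyc_era")
  bin <- cut(v$t_months, breaks, include.lowest = TRUE, right = FALSE)
  out <- NULL
  for (b in levels(bin)) {
    rows <- list()
    for (g in c("never_not_yet", "cyc_era")) {
      i <- which(bin == b & grp == g)
      x <- v[[measure]][i]
      un <- wtd_mean_ci(x, rep(1, length(i)), level)
      wt <- wtd_mean_ci(x, w[i], level)
      rows[[g]] <- data.frame(
        bin = b, group = g, n = un[["n"]], empty = un[["n"]] == 0,
        mean_unweighted = un[["mean"]], lo_unweighted = un[["lo"]],
        hi_unweighted = un[["hi"]],
        mean_weighted = wt[["mean"]], lo_weighted = wt[["lo"]],
        hi_weighted = wt[["hi"]], stringsAsFactors = FALSE)
    }
    sd_pool <- stats::sd(v[[measure]][bin == b], na.rm = TRUE)
    rr <- rbind(rows[[1]], rows[[2]])
    rr$std_diff_unweighted <-
      abs(rows[[1]]$mean_unweighted - rows[[2]]$mean_unweighted) / sd_pool
    rr$std_diff_weighted <-
      abs(rows[[1]]$mean_weighted - rows[[2]]$mean_weighted) / sd_pool
    out <- rbind(out, rr)
  }
  rownames(out) <- NULL
  out
}
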