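#' Longitudinal juvenile dermatomyositis cohort tables
#'
#' A `cohort_table` is the common currency of the pipeline: a per-patient
#' table plus a long-format visit table (one row per patient-visit), with
#' validity rules enforced at construction.
#'
#' Time is measured in months since diagnosis (diagnosis = 0), continuous.
#' Disease-activity scores follow their clinical ranges: the modified skin
#' Disease Activity Score `das` in \[0, 5\] (higher = worse skin disease), the
#' physician's global assessment `pga` in \[0, 10\] (higher = worse), and the
#' Childhood Myositis Assessment Scale `cmas` in \[0, 52\] (lower = worse
#' muscle disease).  `gc_dose` is the oral glucocorticoid dose in mg/day.
#'
#' @section Patient table columns:
#' `patient_id`, `sex` ("female"/"male"), `age_at_diagnosis_years`,
#' `cyc_start_months`, `cyc_stop_months` (NA when the patient never received
#' cyclophosphamide), and ever-recorded feature flags `calcinosis`,
#' `ulceration`, `lipoatrophy`, `abnormal_respiration`, `edema`.
#'
#' @section Visit table columns:
#' `patient_id`, `t_months`, `das`, `pga`, `cmas`, `gc_dose_mg_day`,
#' `on_cyc`, and concomitant-medication flags `oral_gc`, `iv_gc`, `mtx`,
#' `ivig`, `hcq`, `aza`, `mmf`, `biologic`.
#'
#' @param patients data frame of per-patient metadata (see below).
#' @param visits data frame of patient-visits (see below); sorted internally
#'   by `(patient_id, t_months)`.
#' @return an object of class `cohort_table`: a list with elements
#'   `patients` and `visits`.
#' @export
cohort_table <- function(patients, visits) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)
  visits <- visits[order(visits$patient_id, visits$t_months), , drop = FALSE]
  rownames(visits) <- NULL
  rownames(patients) <- NULL
  x <- structure(list(patients = patients, visits = visits),
                 class = "cohort_table")
  validate_cohort(x)
  x
}

med_flag_cols <- c("oral_gc", "iv_gc", "mtx", "ivig", "hcq", "aza", "mmf",
                   "biologic")
feature_cols <- c("calcinosis", "ulceration", "lipoatrophy",
                  "abnormal_respiration", "edema")
visit_cols <- c("patient_id", "t_months", "das", "pga", "cmas",
                "gc_dose_mg_day", "on_cyc", med_flag_cols)
patient_cols <- c("patient_id", "sex", "age_at_diagnosis_years",
                  "cyc_start_months", "cyc_stop_months", feature_cols)

#' Validate a cohort table
#'
#' Checks every structural invariant: schema, score ranges, strictly
#' increasing visit times per patient, referential integrity of
#' `patient_id`, consistency of `on_cyc` with the recorded treatment window
#' (`on_cyc` true exactly when `cyc_start <= t < cyc_stop`), and absence of
#' re-treatment (a second course cannot be represented; the treatment-recency
#' coding is undefined for it).
#'
#' @param x a `cohort_table`.
#' @return `x`, invisibly; errors describe the offending column/row.
#' @export
validate_cohort <- function(x) {
  p <- x$patients; v <- x$visits
  miss <- setdiff(patient_cols, names(p))
  if (length(miss) > 0)
    stopf("patient table is missing column(s): %s", paste(miss, collapse = ", "))
  miss <- setdiff(visit_cols, names(v))
  if (length(miss) > 0)
    stopf("visit table is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(p$patient_id))
    stopf("duplicate patient_id in patient table")
  key <- paste(v$patient_id, v$t_months)
  if (anyDuplicated(key))
    stopf("duplicate (patient_id, t_months) in visit table: %s",
          key[anyDuplicated(key)][1])
  orphan <- setdiff(v$patient_id, p$patient_id)
  if (length(orphan) > 0)
    stopf("visit rows reference unknown patient_id: %s", orphan[1])

  if (any(v$t_months < 0, na.rm = TRUE))
    stopf("negative t_months at visit row %s", which(v$t_months < 0)[1])
  for (sc in c("das", "pga", "cmas")) {
    r <- score_ranges[[sc]]
    bad <- which(!is.na(v[[sc]]) & (v[[sc]] < r[1] | v[[sc]] > r[2]))
    if (length(bad) > 0)
      stopf("%s = %s out of range [%g, %g] at visit row %d (patient %s)",
            sc, v[[sc]][bad[1]], r[1], r[2], bad[1], v$patient_id[bad[1]])
  }
  bad <- which(!is.na(v$gc_dose_mg_day) & v$gc_dose_mg_day < 0)
  if (length(bad) > 0)
    stopf("negative gc_dose_mg_day at visit row %d", bad[1])

  # treatment window invariants
  if (any(!is.na(p$cyc_stop_months) & is.na(p$cyc_start_months)))
    stopf("cyc_stop_months present without cyc_start_months")
  if (any(p$cyc_start_months < 0, na.rm = TRUE))
    stopf("negative cyc_start_months")
  both <- !is.na(p$cyc_start_months) & !is.na(p$cyc_stop_months)
  if (any(p$cyc_stop_months[both] <= p$cyc_start_months[both]))
    stopf("cyc_stop_months must exceed cyc_start_months")

  # on_cyc must agree with the recorded treatment window wherever the start
  # date is known; visits flagged on_cyc with an unknown start date encode
  # "received CYC, date unknown" and are handled by the eligibility filter
  start <- p$cyc_start_months[match(v$patient_id, p$patient_id)]
  stop_ <- p$cyc_stop_months[match(v$patient_id, p$patient_id)]
  expect_on <- !is.na(start) & v$t_months >= start &
    (is.na(stop_) | v$t_months < stop_)
  bad <- which(as.logical(v$on_cyc) != expect_on & !is.na(start))
  if (length(bad) > 0)
    stopf(paste0("on_cyc inconsistent with cyc_start/cyc_stop at visit row %d ",
                 "(patient %s); a second treatment course cannot be ",
                 "represented"), bad[1], v$patient_id[bad[1]])

  for (pid in unique(v$patient_id)) {
    tt <- v$t_months[v$patient_id == pid]
    if (is.unsorted(tt, strictly = TRUE))
      stopf("visit times not strictly increasing for patient %s", pid)
  }
  invisible(x)
}

#' @export
print.cohort_table <- function(x, ...) {
  p <- x$patients
  n_tr <- sum(!is.na(p$cyc_start_months))
  cat(sprintf("cohort_table: %d patients (%d CYC-treated), %d visits\n",
              nrow(p), n_tr, nrow(x$visits)))
  cat(sprintf("  follow-up: median %.1f months; visits/patient: median %g\n",
              stats::median(tapply(x$visits$t_months, x$visits$patient_id, max)),
              stats::median(as.integer(table(x$visits$patient_id)))))
  invisible(x)
}

#' Read a cohort from delimited text files
#'
#' Reads the interchange format: a visit file (one row per patient-visit)
#' and a sidecar patient file.  Empty cells are missing values; score cells
#' that fail to parse as numbers are recorded as missing and counted in the
#' load report attached as attribute `"load_report"`.
#'
#' @param visit_file,patient_file paths to delimited text files.
#' @param sep field separator (default `","`).
#' @return a validated `cohort_table` with a `load_report` attribute giving
#'   the number of unparseable cells per column.
#' @export
read_cohort <- function(visit_file, patient_file, sep = ",") {
  if (!file.exists(visit_file)) stopf("visit file not found: %s", visit_file)
  if (!file.exists(patient_file)) stopf("patient file not found: %s", patient_file)
  v <- utils::read.table(visit_file, header = TRUE, sep = sep,
                         colClasses = "character", na.strings = "",
                         stringsAsFactors = FALSE)
  p <- utils::read.table(patient_file, header = TRUE, sep = sep,
                         colClasses = "character", na.strings = "",
                         stringsAsFactors = FALSE)
  miss <- setdiff(visit_cols, names(v))
  if (length(miss) > 0)
    stopf("visit file is missing column(s): %s", paste(miss, collapse = ", "))
  miss <- setdiff(patient_cols, names(p))
  if (length(miss) > 0)
    stopf("patient file is missing column(s): %s", paste(miss, collapse = ", "))

  report <- list()
  num <- function(df, col) {
    raw <- df[[col]]
    out <- suppressWarnings(as.numeric(raw))
    n_bad <- sum(is.na(out) & !is.na(raw))
    if (n_bad > 0) report[[col]] <<- n_bad
    out
  }
  lgl <- function(df, col) {
    out <- tolower(trimws(df[[col]])) %in% c("true", "t", "1", "yes")
    out[is.na(df[[col]])] <- FALSE
    out
  }
  for (col in c("t_months", "das", "pga", "cmas", "gc_dose_mg_day"))
    v[[col]] <- num(v, col)
  for (col in c("on_cyc", med_flag_cols)) v[[col]] <- lgl(v, col)
  for (col in c("age_at_diagnosis_years", "cyc_start_months", "cyc_stop_months"))
    p[[col]] <- num(p, col)
  for (col in feature_cols) p[[col]] <- lgl(p, col)
  if (any(is.na(v$t_months))) stopf("unparseable t_months in visit file")

  x <- cohort_table(p, v)
  attr(x, "load_report") <- report
  x
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: missing values become empty cells, logicals
#' are written as `TRUE`/`FALSE`.
#'
#' @param cohort a `cohort_table`.
#' @param visit_file,patient_file output paths.
#' @param sep field separator.
#' @return the paths, invisibly.
#' @export
write_cohort <- function(cohort, visit_file, patient_file, sep = ",") {
  utils::write.table(cohort$visits[, visit_cols], visit_file, sep = sep,
                     na = "", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$patients[, patient_cols], patient_file, sep = sep,
                     na = "", row.names = FALSE, quote = FALSE)
  invisible(c(visit_file, patient_file))
}

#' Apply the incident-case eligibility filter
#'
#' Retains patients whose first recorded visit is no more than
#' `max_first_visit` months after diagnosis (strictly greater is excluded)
#' and whose cyclophosphamide start date is known whenever they ever
#' received the drug.  Ever-received is inferred from any `on_cyc` visit
#' flag or a recorded `cyc_stop_months`.
#'
#' @param cohort a `cohort_table`.
#' @param max_first_visit months; default 3.
#' @return the filtered `cohort_table` with attribute `"exclusions"`, a data
#'   frame of `patient_id` and `reason`.  An error is raised if no patient
#'   survives the filter.
#' @export
apply_eligibility <- function(cohort, max_first_visit = 3) {
  p <- cohort$patients; v <- cohort$visits
  first_t <- tapply(v$t_months, v$patient_id, min)
  ever_on <- tapply(v$on_cyc, v$patient_id, any)
  excl <- data.frame(patient_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(p))) {
    pid <- p$patient_id[i]
    ft <- first_t[[pid]]
    if (is.null(ft) || is.na(ft)) {
      excl <- rbind(excl, data.frame(patient_id = pid, reason = "no visits"))
      next
    }
    if (ft > max_first_visit) {
      excl <- rbind(excl, data.frame(
        patient_id = pid,
        reason = sprintf("first visit at %.2f months exceeds %g months",
                         ft, max_first_visit)))
      next
    }
    received <- isTRUE(ever_on[[pid]]) || !is.na(p$cyc_stop_months[i])
    if (received && is.na(p$cyc_start_months[i])) {
      excl <- rbind(excl, data.frame(patient_id = pid,
                                     reason = "CYC received but start date unknown"))
    }
  }
  keep <- setdiff(p$patient_id, excl$patient_id)
  if (length(keep) == 0)
    stopf("no patients remain after eligibility filtering (%d excluded)",
          nrow(excl))
  out <- cohort_table(p[p$patient_id %in% keep, , drop = FALSE],
                      v[v$patient_id %in% keep, , drop = FALSE])
  attr(out, "exclusions") <- excl
  out
}

#' Nearest visit to a nominal time point
#'
#' Selects, among one patient's visits, the visit closest to a nominal time
#' within a symmetric window (the descriptive analysis aligns visits to
#' ~0/6/12/24 months after treatment start, within about 2 months before or
#' after).  Ties between two equidistant visits are resolved to the earlier
#' visit, deterministically.
#'
#' @param visits data frame of one patient's visits (visit-table columns),
#'   sorted by `t_months`.
#' @param nominal nominal time, in the same units/origin as `visits$t_months`.
#' @param window half-width of the admissible window in months (default 2).
#' @return the selected visit row (a one-row data frame), or `NULL` when no
#'   visit falls within the window.
#' @export
nearest_visit <- function(visits, nominal, window = 2) {
  d <- abs(visits$t_months - nominal)
  ok <- which(d <= window)
  if (length(ok) == 0) return(NULL)
  best <- ok[order(d[ok], visits$t_months[ok])][1]
  visits[best, , drop = FALSE]
}

#' Split-time treatment-recency categories
#'
#' Levels, in their natural order, of the categorical covariate coding how
#' recently a cyclophosphamide course was started: never/not yet, within the
#' last 6 months, 6-12 months ago, more than 12 months ago.
#' @export
split_time_levels <- c("never_not_yet", "cyc_le_6mo", "cyc_6_12mo",
                       "cyc_gt_12mo")

#' Code treatment recency ("split time") for patient-visits
#'
#' Maps time since diagnosis and treatment start to the four-level
#' treatment-recency factor.  Intervals are half-open so the levels
#' partition the time axis: `never_not_yet` when treatment never started or
#' `t < cyc_start`; `cyc_le_6mo` when `0 <= t - cyc_start <= 6`;
#' `cyc_6_12mo` when `6 < t - cyc_start <= 12`; `cyc_gt_12mo` beyond 12
#' months.  For any treated patient the category is a non-decreasing step
#' function of time.
#'
#' @param t months since diagnosis (vector, >= 0).
#' @param cyc_start months since diagnosis of treatment start (vector,
#'   recycled; `NA` = never treated).
#' @return a factor with levels [split_time_levels].
#' @export
split_time <- function(t, cyc_start) {
  if (any(t < 0, na.rm = TRUE)) stopf("negative t in split_time()")
  n <- max(length(t), length(cyc_start))
  t <- rep_len(t, n); cyc_start <- rep_len(cyc_start, n)
  since <- t - cyc_start
  out <- rep(split_time_levels[1], n)
  out[!is.na(since) & since >= 0 & since <= 6] <- split_time_levels[2]
  out[!is.na(since) & since > 6 & since <= 12] <- split_time_levels[3]
  out[!is.na(since) & since > 12] <- split_time_levels[4]
  factor(out, levels = split_time_levels)
}

# Internal: visits joined with the patient metadata columns the models use,
# plus the split-time factor.  One row per visit, ordered (patient, t).
visit_frame <- function(cohort) {
  v <- cohort$visits
  p <- cohort$patients
  i <- match(v$patient_id, p$patient_id)
  v$age <- p$age_at_diagnosis_years[i]
  v$sex <- p$sex[i]
  v$cyc_start <- p$cyc_start_months[i]
  v$cyc_stop <- p$cyc_stop_months[i]
  v$st <- split_time(v$t_months, v$cyc_start)
  v
}
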