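#' Unadjusted descriptive test battery
#'
#' Group comparisons and repeated-measures tests used in the unadjusted
#' analysis: 2x2 contingency tests (chi-square with continuity correction,
#' Fisher exact), two-sample rank-sum comparisons, Friedman nonparametric
#' repeated-measures ANOVA over nominal time points, Wilcoxon signed-rank
#' post hocs with Bonferroni correction, and median/IQR change summaries.
#'
#' All tests return a lightweight `cyc_test` result with fields
#' `statistic`, `df`, `p_value`, `method`, `n_used`.
#'
#' @name descriptive
NULL

new_test_result <- function(statistic, df, p_value, method, n_used) {
  structure(list(statistic = unname(statistic), df = df,
                 p_value = unname(p_value), method = method, n_used = n_used),
            class = "cyc_test")
}

#' @export
print.cyc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, p = %.4g (n = %d)\n", x$method,
              format(x$statistic, digits = 4),
              if (is.null(x$df)) "-" else x$df, x$p_value, x$n_used))
  invisible(x)
}

#' 2x2 contingency-table test
#'
#' Compares two proportions from a 2x2 table of counts
#' \code{rbind(c(a, b), c(c, d))} where rows are groups and columns
#' outcome/no-outcome.  `chi2_cc` is the Pearson chi-square test with
#' Yates' continuity correction (df = 1); `fisher` is the exact test with
#' two-sided p-value by the probability-mass method (sum of hypergeometric
#' probabilities of tables at most as probable as the one observed).
#'
#' @param a,b,c,d nonnegative counts.
#' @param method `"chi2_cc"` or `"fisher"`.
#' @return a `cyc_test`.
#' @examples
#' two_by_two_test(21, 35, 21, 123)  # p = 0.00073
#' @export
two_by_two_test <- function(a, b, c, d, method = c("chi2_cc", "fisher")) {
  method <- match.arg(method)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be nonnegative integers")
  if (sum(counts) == 0) stopf("empty table")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (method == "chi2_cc") {
    if (any(rowSums(m) == 0) || any(colSums(m) == 0))
      stopf("chi-square test undefined: a table margin is zero")
    res <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    new_test_result(res$statistic, 1L, res$p.value,
                    "chi-square test with continuity correction", sum(counts))
  } else {
    if (any(rowSums(m) == 0) || any(colSums(m) == 0))
      return(new_test_result(NA_real_, NULL, 1, "Fisher's exact test",
                             sum(counts)))
    res <- stats::fisher.test(m)
    new_test_result(unname(res$estimate), NULL, res$p.value,
                    "Fisher's exact test", sum(counts))
  }
}

#' Two-sample rank-sum comparison
#'
#' Wilcoxon-Mann-Whitney comparison of two independent samples, two-sided.
#' Uses exact enumeration when the combined sample size is at most 10 and
#' there are no ties; otherwise the normal approximation with continuity
#' and tie correction.
#'
#' @param x,y numeric samples (each nonempty).
#' @return a `cyc_test`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stopf("both samples must be nonempty")
  n <- length(x) + length(y)
  if (length(unique(c(x, y))) == 1)
    return(new_test_result(length(x) * length(y) / 2, NULL, 1,
                           "Wilcoxon rank-sum test", n))
  ties <- anyDuplicated(c(x, y)) > 0
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = (n <= 10 && !ties), correct = TRUE))
  new_test_result(res$statistic, NULL, res$p.value,
                  "Wilcoxon rank-sum test", n)
}

#' Friedman repeated-measures test
#'
#' Nonparametric repeated-measures analysis of variance on an
#' `n blocks x k conditions` matrix (patients x nominal time points).
#' Rows containing any missing value are dropped (complete-case).  The
#' statistic uses within-block mid-ranks with tie correction and is
#' referred to a chi-square distribution with `k - 1` df; with
#' `exact = TRUE` the p-value is instead computed by full enumeration of
#' all `(k!)^n` equally likely within-block rank permutations (only
#' feasible for small `n`).
#'
#' @param block_matrix numeric matrix, blocks in rows, conditions in columns.
#' @param exact compute the permutation p-value instead of the chi-square
#'   approximation.
#' @return a `cyc_test` (with `n_used` the number of complete blocks).
#' @export
friedman_rm_test <- function(block_matrix, exact = FALSE) {
  m <- as.matrix(block_matrix)
  if (ncol(m) < 3) stopf("need k >= 3 conditions")
  cc <- stats::complete.cases(m)
  m <- m[cc, , drop = FALSE]
  if (nrow(m) < 2) stopf("insufficient data: fewer than 2 complete blocks")
  if (all(apply(m, 1, function(r) max(r) == min(r))))
    return(new_test_result(0, ncol(m) - 1L, 1,
                           "Friedman test", nrow(m)))
  res <- stats::friedman.test(m)
  stat <- unname(res$statistic)
  if (!exact)
    return(new_test_result(stat, unname(res$parameter), res$p.value,
                           "Friedman test", nrow(m)))
  # enumeration over all within-block permutations of the observed values
  k <- ncol(m); n <- nrow(m)
  perms <- as.matrix(expand.grid(rep(list(seq_len(factorial(k))), n)))
  all_perm <- permutations_of(k)
  stat_of <- function(mm) unname(stats::friedman.test(mm)$statistic)
  count <- 0L
  total <- nrow(perms)
  mm <- m
  for (r in seq_len(total)) {
    for (b in seq_len(n)) mm[b, ] <- m[b, all_perm[[perms[r, b]]]]
    if (stat_of(mm) >= stat - 1e-12) count <- count + 1L
  }
  new_test_result(stat, unname(res$parameter), count / total,
                  "Friedman test (exact permutation)", n)
}

# All permutations of 1..k, built by inserting k into each position of the
# permutations of 1..(k-1).
permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (s in permutations_of(k - 1))
    for (pos in 0:(k - 1))
      out[[length(out) + 1L]] <- append(s, k, after = pos)
  out
}

#' Wilcoxon signed-rank post hoc comparisons
#'
#' All pairwise signed-rank comparisons between the columns of a complete
#' `n x k` block matrix (e.g. scores at nominal 0/6/12/24 months), with a
#' Bonferroni significance threshold of `alpha / m` over the `m = k(k-1)/2`
#' pairs.  Zero differences are dropped before ranking (classical
#' convention).  Exact p-values when at most 15 nonzero differences and no
#' tied absolute differences; otherwise the normal approximation.
#'
#' @param block_matrix numeric matrix, complete cases used per pair.
#' @param alpha family significance level (default 0.05).
#' @return data frame with one row per pair: `pair`, `statistic`,
#'   `p_value`, `n_nonzero`, `significant` (p < alpha/m), and attribute
#'   `"threshold"`.
#' @export
signed_rank_posthoc <- function(block_matrix, alpha = 0.05) {
  m <- as.matrix(block_matrix)
  k <- ncol(m)
  if (k < 2) stopf("need at least 2 conditions")
  cn <- colnames(m) %||% paste0("T", seq_len(k))
  pairs <- utils::combn(k, 2)
  m_tests <- ncol(pairs)
  thr <- bonferroni_threshold(alpha, m_tests)
  out <- data.frame(pair = character(0), statistic = numeric(0),
                    p_value = numeric(0), n_nonzero = integer(0),
                    significant = logical(0), stringsAsFactors = FALSE)
  for (j in seq_len(m_tests)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    cc <- stats::complete.cases(m[, c(i1, i2)])
    d <- m[cc, i2] - m[cc, i1]
    res <- signed_rank_test(d)
    out <- rbind(out, data.frame(
      pair = paste(cn[i1], "vs", cn[i2]), statistic = res$statistic,
      p_value = res$p_value, n_nonzero = res$n_used,
      significant = res$p_value < thr, stringsAsFactors = FALSE))
  }
  attr(out, "threshold") <- thr
  out
}

#' One-sample Wilcoxon signed-rank test on paired differences
#'
#' Two-sided test that the paired differences are symmetric about zero.
#' Zeros are dropped; exact when at most 15 nonzero differences with no
#' tied magnitudes, otherwise normal approximation with continuity
#' correction.  All-zero differences give p = 1 with a warning.
#'
#' @param d numeric vector of paired differences (at least one nonzero to
#'   be informative).
#' @return a `cyc_test` (`n_used` = number of nonzero differences).
#' @export
signed_rank_test <- function(d) {
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    warnf("all paired differences are zero")
    return(new_test_result(0, NULL, 1, "Wilcoxon signed-rank test", 0L))
  }
  ties <- anyDuplicated(abs(nz)) > 0
  res <- suppressWarnings(
    stats::wilcox.test(nz, exact = (length(nz) <= 15 && !ties),
                       correct = TRUE))
  new_test_result(res$statistic, NULL, min(res$p.value, 1),
                  "Wilcoxon signed-rank test", length(nz))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise level.
#' @param m number of independent tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 14)  # 0.00357..., printed as 0.0036
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stopf("m must be >= 1")
  alpha / m
}

#' Median/IQR change summary at nominal months after treatment start
#'
#' For the treated patients, aligns visits to nominal time points relative
#' to the treatment start date using [nearest_visit()] and summarises a
#' disease-activity measure: per nominal time, the number of patients with
#' a usable score, median, quartiles, and the missing percentage (patients
#' with no qualifying visit or a missing score at the matched visit).  Also
#' returns the complete-case block matrix feeding [friedman_rm_test()].
#'
#' @param cohort a `cohort_table`.
#' @param measure one of `"das"`, `"pga"`, `"cmas"`, `"gc_dose_mg_day"`.
#' @param nominal nominal months after treatment start (default 0/6/12/24).
#' @param window alignment half-window, months (default 2).
#' @return list with `summary` (data frame, one row per nominal time),
#'   `blocks` (patients x time-points score matrix, `NA` where missing) and
#'   `friedman` (a `cyc_test` on the complete cases).
#' @export
change_summary <- function(cohort, measure = c("das", "pga", "cmas",
                                               "gc_dose_mg_day"),
                           nominal = c(0, 6, 12, 24), window = 2) {
  measure <- match.arg(measure)
  p <- cohort$patients
  treated <- p$patient_id[!is.na(p$cyc_start_months)]
  if (length(treated) == 0) stopf("no treated patients in cohort")
  blocks <- matrix(NA_real_, nrow = length(treated), ncol = length(nominal),
                   dimnames = list(treated, paste0("m", nominal)))
  for (pid in treated) {
    vv <- cohort$visits[cohort$visits$patient_id == pid, , drop = FALSE]
    start <- p$cyc_start_months[p$patient_id == pid]
    for (j in seq_along(nominal)) {
      hit <- nearest_visit(vv, start + nominal[j], window)
      if (!is.null(hit)) blocks[pid, j] <- hit[[measure]]
    }
  }
  summ <- data.frame(
    nominal_month = nominal,
    n = colSums(!is.na(blocks)),
    median = apply(blocks, 2, stats::median, na.rm = TRUE),
    q1 = apply(blocks, 2, stats::quantile, probs = 0.25, na.rm = TRUE,
               names = FALSE),
    q3 = apply(blocks, 2, stats::quantile, probs = 0.75, na.rm = TRUE,
               names = FALSE),
    pct_missing = round(100 * colMeans(is.na(blocks)), 1),
    row.names = NULL)
  fr <- tryCatch(friedman_rm_test(blocks), error = function(e) NULL)
  list(summary = summ, blocks = blocks, friedman = fr)
}
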