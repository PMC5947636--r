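# Builders for small hand-made cohorts used across the test files.

make_patient <- function(id, sex = "female", age = 7, cyc_start = NA,
                         cyc_stop = NA) {
  data.frame(patient_id = id, sex = sex, age_at_diagnosis_years = age,
             cyc_start_months = cyc_start, cyc_stop_months = cyc_stop,
             calcinosis = FALSE, ulceration = FALSE, lipoatrophy = FALSE,
             abnormal_respiration = FALSE, edema = FALSE,
             stringsAsFactors = FALSE)
}

make_visits <- function(id, t, das = 2, pga = 4, cmas = 30, gc = NA_real_,
                        on_cyc = FALSE) {
  k <- length(t)
  data.frame(patient_id = id, t_months = t,
             das = rep_len(das, k), pga = rep_len(pga, k),
             cmas = rep_len(cmas, k), gc_dose_mg_day = rep_len(gc, k),
             on_cyc = rep_len(on_cyc, k),
             oral_gc = TRUE, iv_gc = FALSE, mtx = TRUE, ivig = FALSE,
             hcq = FALSE, aza = FALSE, mmf = FALSE, biologic = FALSE,
             stringsAsFactors = FALSE)
}

# 3 patients: one treated (course 1->6.5 months), one never treated, one
# late first visit (ineligible).
tiny_cohort <- function() {
  p <- rbind(make_patient("A", cyc_start = 1, cyc_stop = 6.5),
             make_patient("B"),
             make_patient("C"))
  va <- make_visits("A", c(0.5, 1, 3, 7, 14), das = c(4, 4, 3, 2, 1),
                    pga = c(7, 6, 5, 3, 2), cmas = c(10, 12, 20, 35, 45))
  va$on_cyc <- c(FALSE, TRUE, TRUE, FALSE, FALSE)
  vb <- make_visits("B", c(0.2, 2, 8, 15), das = 2, pga = 3, cmas = 40)
  vc <- make_visits("C", c(4, 9), das = 3, pga = 5, cmas = 25)
  cohort_table(p, rbind(va, vb, vc))
}

# A fast small simulation configuration for structural tests.
fast_config <- function(seed = 1, n = 60, ...) {
  sim_config(n_patients = n, followup_years = 3, seed = seed, ...)
}
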