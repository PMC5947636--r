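test_that("cohort round-trips through the delimited interchange format", {
  co <- tiny_cohort()
  vf <- tempfile(fileext = ".csv"); pf <- tempfile(fileext = ".csv")
  write_cohort(co, vf, pf)
  back <- read_cohort(vf, pf)
  expect_equal(back$visits, co$visits)
  expect_equal(back$patients, co$patients)
  expect_equal(length(attr(back, "load_report")), 0)
})

test_that("empty cells read as missing and unparseable scores are reported", {
  co <- tiny_cohort()
  co$visits$pga[2] <- NA
  vf <- tempfile(fileext = ".csv"); pf <- tempfile(fileext = ".csv")
  write_cohort(co, vf, pf)
  txt <- readLines(vf)
  txt[4] <- sub("^(([^,]*,){3})[^,]*", "\\1not_a_number", txt[4])
  writeLines(txt, vf)
  back <- read_cohort(vf, pf)
  expect_true(is.na(back$visits$pga[2]))
  expect_equal(attr(back, "load_report")$pga, 1)
})

test_that("validation rejects out-of-range scores, duplicates and re-treatment", {
  co <- tiny_cohort()
  bad <- co; bad$visits$das[3] <- 7
  expect_error(validate_cohort(bad), "das = 7.*row 3")
  bad <- co; bad$visits$t_months[2] <- bad$visits$t_months[1]
  expect_error(cohort_table(bad$patients, bad$visits), "duplicate")
  # a second course cannot be represented: on/off/on pattern is inconsistent
  bad <- co
  bad$visits$on_cyc[bad$visits$patient_id == "A"] <-
    c(FALSE, TRUE, FALSE, TRUE, FALSE)
  expect_error(validate_cohort(bad), "second treatment course")
  # visit referencing an unknown patient
  bad <- co; bad$visits$patient_id[1] <- "ZZ"
  expect_error(cohort_table(co$patients, bad$visits), "unknown patient_id")
})

test_that("schema errors name the missing column", {
  co <- tiny_cohort()
  vf <- tempfile(fileext = ".csv"); pf <- tempfile(fileext = ".csv")
  write_cohort(co, vf, pf)
  tab <- utils::read.csv(vf)
  tab$cmas <- NULL
  utils::write.csv(tab, vf, row.names = FALSE)
  expect_error(read_cohort(vf, pf), "cmas")
})

test_that("eligibility keeps early-presenting patients with known start dates", {
  co <- tiny_cohort()
  out <- apply_eligibility(co)
  excl <- attr(out, "exclusions")
  expect_setequal(out$patients$patient_id, c("A", "B"))
  expect_equal(excl$patient_id, "C")
  expect_match(excl$reason, "exceeds 3")
  # treated patient (on_cyc flags) with unknown start date is excluded
  co2 <- tiny_cohort()
  co2$patients$cyc_start_months[1] <- NA
  co2$patients$cyc_stop_months[1] <- NA
  out2 <- apply_eligibility(co2)
  excl2 <- attr(out2, "exclusions")
  expect_true("A" %in% excl2$patient_id)
  expect_match(excl2$reason[excl2$patient_id == "A"], "start date unknown")
  co3 <- tiny_cohort()
  co3$patients$cyc_start_months[1] <- NA      # stop recorded, start unknown
  expect_error(validate_cohort(co3), "cyc_stop_months")
})

test_that("eligibility is idempotent and partitions the cohort", {
  co <- tiny_cohort()
  once <- apply_eligibility(co)
  twice <- apply_eligibility(once)
  expect_equal(twice$patients, once$patients)
  expect_equal(nrow(attr(twice, "exclusions")), 0)
  expect_setequal(c(once$patients$patient_id,
                    attr(once, "exclusions")$patient_id),
                  co$patients$patient_id)
  # everyone filtered out is an explicit error, not an empty success
  late <- cohort_table(make_patient("Z"),
                       make_visits("Z", c(5, 9)))
  expect_error(apply_eligibility(late), "no patients remain")
})

test_that("nearest_visit picks the closest visit inside the window", {
  v <- make_visits("A", c(4.5, 7.9))
  expect_equal(nearest_visit(v, 6)$t_months, 4.5)
  expect_null(nearest_visit(make_visits("A", 8.5), 6))
  # equidistant tie resolved to the earlier visit
  expect_equal(nearest_visit(make_visits("A", c(5, 7)), 6)$t_months, 5)
  # property: never outside the window
  set.seed(4)
  for (i in 1:25) {
    tv <- sort(runif(6, 0, 30))
    hit <- nearest_visit(make_visits("A", tv), nominal = 12, window = 2)
    if (!is.null(hit)) expect_lte(abs(hit$t_months - 12), 2)
  }
})

test_that("split time codes treatment recency with half-open boundaries", {
  expect_equal(as.character(split_time(10, NA)), "never_not_yet")
  expect_equal(as.character(split_time(c(3, 9, 15) + 2, 2)),
               c("cyc_le_6mo", "cyc_6_12mo", "cyc_gt_12mo"))
  expect_equal(as.character(split_time(8, 2)), "cyc_le_6mo")   # exactly 6
  expect_equal(as.character(split_time(14, 2)), "cyc_6_12mo")  # exactly 12
  expect_equal(as.character(split_time(1, 2)), "never_not_yet")
  expect_error(split_time(-1, NA), "negative")
  # non-decreasing step function of t for any treated trajectory
  set.seed(9)
  for (i in 1:25) {
    tv <- sort(runif(12, 0, 40))
    st <- as.integer(split_time(tv, cyc_start = runif(1, 0, 10)))
    expect_true(all(diff(st) >= 0))
  }
})
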