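test_that("hand-counted components decide MS-ATP status", {
  # male: waist 105 (> 102), Tg 2.0, HDL 1.5, BP 120/70 untreated, glucose 5.0
  s <- make_subject(waist = 105, glucose = 5.0)
  r <- classify_mets(s, tg_value = 2.0, mets_thresholds("atp"))
  expect_equal(r$n_positive, 2)          # waist + Tg only
  expect_false(r$status)
  # raising glucose to 6.0 adds the third component
  r2 <- classify_mets(make_subject(waist = 105, glucose = 6.0), 2.0,
                      mets_thresholds("atp"))
  expect_equal(r2$n_positive, 3)
  expect_true(r2$status)
})

test_that("Tg 1.7 mmol/L is component-positive under all three criteria", {
  s <- make_subject()
  for (cr in c("atp", "idf", "idftf")) {
    expect_true(classify_mets(s, 1.7, mets_thresholds(cr))$tg_pos, label = cr)
    expect_false(classify_mets(s, 1.699, mets_thresholds(cr))$tg_pos,
                 label = cr)
  }
})

test_that("mandatory waist separates MS-IDF from MS-IDFTF", {
  # male waist 90: below the 94 cm IDF/IDFTF cut; all four other components
  # positive
  s <- make_subject(waist = 90, sbp = 140, glucose = 6.5, hdl = 0.9)
  expect_false(classify_mets(s, 2.5, mets_thresholds("idf"))$status)
  expect_true(classify_mets(s, 2.5, mets_thresholds("idftf"))$status)
  # ATP waist cut is strict: exactly 102 cm is negative, 94 is for IDF
  expect_false(classify_mets(make_subject(waist = 102), 1.0,
                             mets_thresholds("atp"))$waist_pos)
  expect_true(classify_mets(make_subject(waist = 94), 1.0,
                            mets_thresholds("idf"))$waist_pos)
})

test_that("drug treatment counts as a positive component", {
  s <- make_subject(lipid_treated = TRUE)      # Tg low, HDL high
  r <- classify_mets(s, 0.8, mets_thresholds("atp"))
  expect_true(r$tg_pos)
  expect_true(r$hdl_pos)
  r2 <- classify_mets(make_subject(bp_treated = TRUE), 0.8,
                      mets_thresholds("atp"))
  expect_true(r2$bp_pos)
  r3 <- classify_mets(make_subject(diabetes_dx = TRUE), 0.8,
                      mets_thresholds("atp"))
  expect_true(r3$glucose_pos)
})

test_that("missing components resolve only when the outcome is forced", {
  th <- mets_thresholds("atp")
  # three positives, two missing: already positive
  s <- make_subject(waist = 110, sbp = NA, glucose = NA, hdl = 0.9)
  r <- classify_mets(s, 2.0, th)
  expect_equal(r$n_missing, 2)
  expect_true(r$status)
  # one positive, one missing: can no longer reach 3 -> negative
  s2 <- make_subject(waist = 110, glucose = NA)
  expect_false(classify_mets(s2, 1.0, th)$status)
  # two positives, two missing: undecidable
  s3 <- make_subject(waist = 110, sbp = NA, glucose = NA)
  expect_true(is.na(classify_mets(s3, 2.0, th)$status))
  # treatment decides a component even when the measurement is missing
  s4 <- make_subject(glucose = NA, diabetes_dx = TRUE)
  expect_true(classify_mets(s4, 1.0, th)$glucose_pos)
  # IDF: waist missing but others below 2 forces negative
  s5 <- make_subject(waist = NA)
  expect_false(classify_mets(s5, 1.0, mets_thresholds("idf"))$status)
  # IDF: waist missing with 2 other positives stays undecidable
  s6 <- make_subject(waist = NA, sbp = 140)
  expect_true(is.na(classify_mets(s6, 2.0, mets_thresholds("idf"))$status))
})

test_that("status is non-decreasing in the supplied Tg for every criteria set", {
  coh <- generate_cohort(quick_config(n = 300, seed = 31))
  tg_grid <- c(0.5, 1.0, 1.69, 1.7, 2.5, 4.0)
  for (cr in c("atp", "idf", "idftf")) {
    th <- mets_thresholds(cr)
    status <- sapply(tg_grid, function(tg)
      classify_mets(coh, rep(tg, nrow(coh)), th)$status)
    for (i in seq_len(ncol(status) - 1)) {
      both <- !is.na(status[, i]) & !is.na(status[, i + 1])
      expect_true(all(status[both, i] <= status[both, i + 1]), label = cr)
    }
  }
})

test_that("the lower harmonized waist cut makes MS-IDFTF at least as prevalent as MS-ATP", {
  for (seed in c(41, 42, 43)) {
    coh <- generate_cohort(quick_config(n = 2000, seed = seed))
    p_atp <- mets_prevalence(coh, "visit2", mets_thresholds("atp"))$prevalence
    p_tf <- mets_prevalence(coh, "visit2", mets_thresholds("idftf"))$prevalence
    expect_gte(p_tf, p_atp)
  }
})

test_that("prevalence arithmetic and the elevation-only ordering", {
  # four subjects, one positive
  coh4 <- do.call(rbind, lapply(1:4, function(i) make_subject(
    waist = c(110, 80, 80, 80)[i], sbp = c(140, 110, 110, 110)[i],
    glucose = c(6.5, 4.5, 4.5, 4.5)[i])))
  coh4$v2_tg <- c(2.0, 0.8, 0.8, 0.8)
  out <- mets_prevalence(coh4, "visit2", mets_thresholds("atp"))
  expect_equal(out$prevalence, 25.0)
  expect_equal(out$n_decidable, 4)
  # all-negative cohort: 0%
  coh0 <- do.call(rbind, lapply(1:3, function(i) make_subject(waist = 70)))
  coh0$v2_tg <- rep(0.5, 3)
  expect_equal(mets_prevalence(coh0, "visit2",
                               mets_thresholds("atp"))$prevalence, 0)

  # subjects held at 2 of 5 positive so the Tg component alone decides:
  # raw (elevated) >= corrected >= fasting prevalence
  n <- 400
  coh <- do.call(rbind, lapply(seq_len(n), function(i)
    make_subject(waist = 110, sbp = 140, glucose = 4.5, hdl = 1.5)))
  set.seed(51)
  coh$v2_tg <- rlnorm(n, log(1.3), 0.4)
  coh$sex <- "male"
  coh$v1_fasting_hours <- sample(2:7, n, TRUE)
  coh$v1_tg <- postprandial_elevate(coh$v2_tg, coh$v1_fasting_hours, coh$sex)
  coh$tg_corrected <- correct_tg(coh$v1_tg, coh$v1_fasting_hours, coh$sex)
  th <- mets_thresholds("atp")
  p <- vapply(c("visit1_raw", "visit1_corrected", "visit2"), function(src)
    mets_prevalence(coh, src, th)$prevalence, numeric(1))
  expect_gte(p[["visit1_raw"]], p[["visit1_corrected"]])
  expect_gte(p[["visit1_corrected"]], p[["visit2"]])
})

test_that("unknown criteria and undecidable cohorts raise errors", {
  expect_error(mets_thresholds("who"))
  expect_error(mets_thresholds("atp", n_required = 6), "2..5")
  s <- make_subject(waist = NA, sbp = NA, glucose = NA, hdl = NA)
  s$v2_tg <- 2.0
  expect_error(mets_prevalence(s, "visit2", mets_thresholds("atp")),
               "undefined")
})
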