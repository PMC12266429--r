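test_that("rates per 1000 follow the published aggregate conventions", {
  expect_equal(rate_per_1000(10, 2), 5000)
  # aggregate arm totals reproduce the arm-level rates
  expect_equal(rate_per_1000(3608, 8276.6), 435.9499, tolerance = 1e-4)
  expect_equal(rate_per_1000(341378, 9647111), 35.3866, tolerance = 1e-4)
  expect_error(rate_per_1000(1, 0), "> 0")
  # scale equivariance
  expect_equal(rate_per_1000(24, 3), 2 * rate_per_1000(12, 3))
  expect_equal(rate_per_1000(24, 6), rate_per_1000(12, 3))
})

test_that("persistent-absence flag is boundary-inclusive and monotone", {
  expect_true(flag_persistent(40, 400))   # exactly 10%
  expect_false(flag_persistent(39, 400))
  expect_true(is.na(flag_persistent(0, 0)))
  # prevalence nonincreasing in the threshold
  set.seed(1)
  miss <- rbinom(500, 300, 0.1); poss <- rep(300, 500)
  prev <- sapply(c(0.05, 0.1, 0.15, 0.2),
                 function(th) mean(flag_persistent(miss, poss, th)))
  expect_true(all(diff(prev) <= 0))
})

test_that("hospital day deduplication is a set union", {
  expect_equal(dedupe_hospital_days(c(1, 2), c(2, 3)), 3)
  expect_equal(dedupe_hospital_days(1:4, 5:6), 6)
  expect_equal(dedupe_hospital_days(7, 7), 1)   # same-day A&E + admission
  expect_equal(dedupe_hospital_days(list(c(1, 2), 7), list(c(2, 3), 7)),
               c(3L, 1L))
})

test_that("score standardisation is within-year with population sd", {
  z <- standardise_scores(c(1, 2, 3), rep("y1", 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # each year re-centred independently
  z2 <- standardise_scores(c(1, 2, 3, 11, 12, 13),
                           rep(c("y1", "y2"), each = 3))
  expect_equal(z2[1:3], z2[4:6], tolerance = 1e-12)
  # joint standardisation of identical cohorts = per-year standardisation
  z3 <- standardise_scores(c(1, 2, 3, 1, 2, 3),
                           rep(c("y1", "y2"), each = 3))
  expect_equal(z3, rep(z, 2), tolerance = 1e-12)
  expect_error(standardise_scores(c(2, 2, 2), rep("y1", 3)), "zero")
  expect_error(standardise_scores(c(2, NA, NA), rep("y1", 3)), ">= 2")
  # missing propagated
  expect_true(is.na(standardise_scores(c(1, 2, NA), rep("y1", 3))[3]))
})

test_that("progress is the z-score difference, absent when either is", {
  expect_equal(progress_score(0.5, 0.5), 0)
  expect_equal(progress_score(-0.7, -0.9), 0.2)
  expect_true(is.na(progress_score(NA, 0.1)))
})

test_that("derived analysis table satisfies its invariants", {
  coh <- generate_cohort(small_config(n = 3000, clusters = 40), seed = 9)
  tbl <- derive_analysis_table(coh)
  # persistent flag equals the >= 10% functional exactly
  missed <- tbl$sessions_medical + tbl$sessions_unauth + tbl$sessions_other
  ok <- tbl$sessions_possible > 0
  expect_identical(tbl$persistent_flag[ok],
                   (missed / tbl$sessions_possible >= 0.10)[ok])
  # within-year z-scores: mean 0, population sd 1
  for (y in unique(tbl$academic_year[!is.na(tbl$ks1_z)])) {
    z <- tbl$ks1_z[tbl$academic_year == y & !is.na(tbl$ks1_z)]
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(mean(z^2), 1, tolerance = 1e-10)
  }
  # masked categorical covariates carry an explicit Unknown level
  expect_true("Unknown" %in% levels(tbl$gest_age))
  expect_false(any(is.na(tbl$gest_age)))
  # median progress near zero
  expect_lt(abs(median(tbl$progress_ks1, na.rm = TRUE)), 0.15)
})

test_that("MCIM expansion zero-fills with indicators and round-trips", {
  tbl <- tibble::tibble(
    treatment = factor(c("None", "Support"), levels = c("None", "Support", "EHCP")),
    eyfsp_z = c(1.5, NA), fsm = factor(c("NotEligible", "Eligible")),
    miss_eyfsp_z = c(0L, 1L)
  )
  out <- apply_mcim(tbl, maskable = "eyfsp_z")
  expect_equal(out$eyfsp_z, c(1.5, 0))
  expect_equal(out$miss_eyfsp_z, c(0L, 1L))
  expect_true("miss_eyfsp_z" %in% attr(out, "mcim_terms"))

  # no missing values: indicators all zero, design unchanged
  tbl2 <- tibble::tibble(eyfsp_z = c(0.3, -0.2))
  out2 <- apply_mcim(tbl2, maskable = "eyfsp_z")
  expect_equal(out2$eyfsp_z, tbl2$eyfsp_z)
  expect_equal(out2$miss_eyfsp_z, c(0L, 0L))
})

test_that("MCIM regression reproduces complete-records fit when nothing is missing", {
  coh <- generate_cohort(small_config(n = 2000, clusters = 30), seed = 14,
                         apply_missingness = FALSE)
  tbl <- apply_mcim(derive_analysis_table(coh))
  cond_mcim <- estimate_conditional(tbl, "ks1")
  cond_cr <- estimate_conditional(complete_records_filter(tbl), "ks1")
  expect_equal(cond_mcim$estimate, cond_cr$estimate, tolerance = 1e-10)
})

test_that("Year-2 restriction truncates totals and drops KS2", {
  coh <- generate_cohort(small_config(n = 2500, clusters = 30), seed = 15)
  tbl <- derive_analysis_table(coh)
  expect_identical(restrict_followup(tbl, 6), tbl)
  r2 <- restrict_followup(tbl, 2)
  expect_true(all(r2$followup_years <= 2))
  expect_identical(r2$hospital_days_unplanned, tbl$hospital_days_unplanned_y2)
  expect_true(all(is.na(r2$ks2_z)))
  expect_true(all(r2$sessions_medical <= tbl$sessions_medical))
  expect_error(restrict_followup(tbl, 4), "horizon")
})

test_that("complete-records filter retains the independent-masking fraction", {
  cfg <- small_config(n = 10000, clusters = 50,
                      missingness = list(
                        birthweight = list(rate = 0.2, slopes = c()),
                        maternal_age = list(rate = 0.2, slopes = c())))
  tbl <- derive_analysis_table(generate_cohort(cfg, seed = 16))
  out <- complete_records_filter(tbl)
  expect_equal(attr(out, "retained_fraction"), 0.64, tolerance = 0.05)
  expect_true(all(out$miss_birthweight == 0 & out$miss_maternal_age == 0))
})
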