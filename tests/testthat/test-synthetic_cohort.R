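test_that("generator is deterministic and respects structural invariants", {
  cfg <- small_config(n = 1500, clusters = 30)
  a <- generate_cohort(cfg, seed = 11)
  b <- generate_cohort(cfg, seed = 11)
  expect_identical(dplyr::select(a, -".sess_py"), dplyr::select(b, -".sess_py"))

  expect_equal(nrow(a), 1500L)
  expect_true(all(a$cluster_id %in% seq_len(30)))
  # absences bounded by possible sessions
  expect_true(all(a$sessions_medical + a$sessions_unauth +
                    a$sessions_other <= a$sessions_possible))
  # same-day dedup: union between max component and component sum,
  # and bounded by the follow-up window
  expect_true(all(a$hospital_days_unplanned <=
                    a$hospital_days_ae + a$hospital_days_apc))
  expect_true(all(a$hospital_days_unplanned >=
                    pmax(a$hospital_days_ae, a$hospital_days_apc) -
                    .Machine$double.eps))
  expect_true(all(a$hospital_days_unplanned <= a$followup_days))
  # KS2 absent for pupils censored before Year 6
  expect_true(all(is.na(a$ks2_raw[a$years_followed < 6])))
})

test_that("covariate-free assignment matches intercept-implied multinomial law", {
  X <- cbind("(Intercept)" = rep(1, 5))
  pr <- assign_treatment(X, list(Support = c("(Intercept)" = log(0.5)),
                                 EHCP = c("(Intercept)" = log(0.1))))$probs[1, ]
  expect_equal(unname(pr), c(1, 0.5, 0.1) / 1.6, tolerance = 1e-12)

  pr0 <- assign_treatment(X, list(Support = c("(Intercept)" = 0),
                                  EHCP = c("(Intercept)" = 0)))$probs[1, ]
  expect_equal(unname(pr0), rep(1 / 3, 3), tolerance = 1e-12)

  # empirical prevalences within 3 binomial SEs at n = 20,000
  cfg <- small_config(n = 20000, clusters = 100)
  for (arm in c("Support", "EHCP")) {
    b <- cfg$ps_coefficients[[arm]]; b[] <- 0
    cfg$ps_coefficients[[arm]] <- b
  }
  cfg$ps_coefficients$Support[["(Intercept)"]] <- log(0.5)
  cfg$ps_coefficients$EHCP[["(Intercept)"]] <- log(0.25)
  coh <- generate_cohort(cfg, seed = 3, apply_missingness = FALSE)
  target <- c(1, 0.5, 0.25) / 1.75
  emp <- as.numeric(prop.table(table(coh$treatment)))
  se <- sqrt(target * (1 - target) / 20000)
  expect_true(all(abs(emp - target) < 3 * se))
})

test_that("default law reproduces the reported arm shares and FSM gradient", {
  coh <- generate_cohort(cohort_config(), seed = 19)
  shares <- prop.table(table(coh$treatment))
  expect_equal(unname(shares[["None"]]), 0.659, tolerance = 0.04)
  expect_equal(unname(shares[["Support"]]), 0.304, tolerance = 0.06)
  expect_equal(unname(shares[["EHCP"]]), 0.037, tolerance = 0.35)
  # Support more common among FSM-eligible pupils
  sup_by_fsm <- tapply(coh$treatment == "Support", coh$fsm, mean)
  expect_gt(sup_by_fsm[["Eligible"]], sup_by_fsm[["NotEligible"]] + 0.05)
})

test_that("count generation hits configured means and the Poisson limit", {
  cfg <- small_config(n = 50000, clusters = 1)
  # isolate one count outcome: zero covariate effects, zero cluster sd
  spec <- cfg$outcome_specs$hosp_ae
  spec$coef[] <- 0; spec$cluster_sd <- 0; spec$effects[] <- 0
  spec$base <- log(1.0)
  for (disp in c(0.4, 1e6)) {
    spec$dispersion <- disp
    cfg$outcome_specs$hosp_ae <- spec
    coh <- generate_cohort(cfg, seed = 8, apply_missingness = FALSE)
    y <- coh$hospital_days_ae; t <- coh$followup_years
    # mean = offset * exp(0): rate 1 per year
    expect_equal(sum(y) / sum(t), 1, tolerance = 0.05)
    # dispersion: var/mean of the per-year counts -> 1 + mu/theta
    y1 <- y[t == 1]
    vm <- var(y1) / mean(y1)
    expected_vm <- 1 + 1 / disp
    expect_equal(vm, expected_vm, tolerance = 0.15)
  }
})

test_that("null treatment effects give equal arm outcomes after balance", {
  cfg <- null_config(n = 30000, clusters = 50)
  # remove confounding too: randomised assignment
  for (arm in c("Support", "EHCP")) {
    b <- cfg$ps_coefficients[[arm]]; b[] <- 0
    b[["(Intercept)"]] <- if (arm == "Support") log(0.5) else log(0.1)
    cfg$ps_coefficients[[arm]] <- b
  }
  coh <- generate_cohort(cfg, seed = 13, apply_missingness = FALSE)
  r <- tapply(coh$hospital_days_unplanned, coh$treatment, sum) /
    tapply(coh$followup_years, coh$treatment, sum)
  expect_equal(unname(r[["Support"]] / r[["None"]]), 1, tolerance = 0.06)
  d <- tapply(coh$ks1_raw, coh$treatment, mean, na.rm = TRUE)
  expect_equal(unname(d[["Support"]] - d[["None"]]), 0, tolerance = 0.05)
})

test_that("MAR masking hits configured rates and errors on unknown covariates", {
  cfg <- small_config(n = 10000, clusters = 50,
                      missingness = list(birthweight = list(rate = 0.2, slopes = c())))
  coh <- generate_cohort(cfg, seed = 4)
  expect_equal(mean(coh$miss_birthweight), 0.2,
               tolerance = 3 * sqrt(0.2 * 0.8 / 10000) / 0.2)
  expect_true(all(is.na(coh$birthweight[coh$miss_birthweight == 1])))

  cfg0 <- small_config(n = 500, clusters = 10,
                       missingness = list(birthweight = list(rate = 0, slopes = c())))
  coh0 <- generate_cohort(cfg0, seed = 4)
  expect_equal(sum(coh0$miss_birthweight), 0L)

  expect_error(cohort_config(missingness = list(not_a_cov = list(rate = 0.1))),
               "unknown covariate")
})

test_that("default missingness concentrates in birth characteristics", {
  coh <- generate_cohort(cohort_config(), seed = 6)
  expect_equal(mean(coh$miss_gest_age), 0.227, tolerance = 0.1)
  expect_equal(mean(coh$miss_birthweight), 0.166, tolerance = 0.12)
  expect_lt(mean(coh$miss_eyfsp_z), 0.03)
})

test_that("config validation rejects malformed generating laws", {
  expect_error(cohort_config(n_pupils = 10, n_clusters = 20))
  expect_error(
    cohort_config(outcome_specs = modifyList(default_outcome_specs(),
      list(hosp_ae = list(family = "gamma", base = 0)))),
    "family")
  expect_error(
    cohort_config(ps_coefficients = list(
      Support = c(no_such_term = 1), EHCP = c("(Intercept)" = 0))),
    "unknown design term")
  bad <- default_outcome_specs()
  bad$hosp_ae$dispersion <- -1
  expect_error(cohort_config(outcome_specs = bad), "dispersion")
})

test_that("cohort CSV round-trips through the JSON sidecar", {
  coh <- generate_cohort(small_config(n = 300, clusters = 10), seed = 2)
  f <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(nrow(back), 300)
  expect_identical(levels(back$treatment), c("None", "Support", "EHCP"))
  expect_equal(back$eyfsp_z, coh$eyfsp_z, tolerance = 1e-9)
  # identical config + seed => byte-identical file
  f2 <- file.path(withr::local_tempdir(), "cohort2.csv")
  write_cohort(generate_cohort(small_config(n = 300, clusters = 10), seed = 2), f2)
  expect_identical(readLines(f), readLines(f2))
})
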