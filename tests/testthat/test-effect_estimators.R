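test_that("IPW weights follow the ATE / ATT definitions", {
  expect_equal(ipw_weights(c(0.5, 0.5), c(1, 0), "ATE")$w, c(2, 2))
  expect_equal(ipw_weights(0.25, 1, "ATE")$w, 4)
  expect_equal(ipw_weights(0.5, 0, "ATT")$w, 1)
  expect_equal(ipw_weights(c(0.2, 0.8), c(1, 1), "ATT")$w, c(1, 1))
  expect_error(ipw_weights(c(0, 0.5), c(1, 0)), "positivity")
})

test_that("intercept-only Poisson recovers the aggregate rate exactly", {
  dat <- tibble::tibble(y = c(3L, 0L, 5L, 2L), t = c(1, 2, 4, 3))
  fit <- fit_outcome_model(dat, "y", "poisson", covariates = character(0),
                           offset = "t")
  expect_equal(exp(unname(coef(fit)[1])), sum(dat$y) / sum(dat$t),
               tolerance = 1e-9)
})

test_that("negative binomial fit estimates dispersion and falls back on equidispersion", {
  set.seed(3)
  n <- 4000
  dat <- tibble::tibble(
    .a = rbinom(n, 1, 0.4),
    t = runif(n, 1, 3)
  )
  dat$y <- rnbinom(n, size = 0.8, mu = exp(0.2 + 0.5 * dat$.a) * dat$t)
  fit <- fit_outcome_model(dat, "y", "negbin", covariates = ".a", offset = "t")
  expect_equal(attr(fit, "family_used"), "negbin")
  expect_equal(fit$theta, 0.8, tolerance = 0.2)
  expect_equal(exp(unname(coef(fit)[".a"])), exp(0.5), tolerance = 0.1)
})

test_that("crude estimators reproduce closed forms from aggregate data", {
  # persistent-absence 2x2: flags matching the published margins
  dat <- tibble::tibble(
    treatment = factor(rep(c("Support", "None"), c(2007, 4347)),
                       levels = c("None", "Support", "EHCP")),
    persistent_flag = c(rep(c(TRUE, FALSE), c(295, 2007 - 295)),
                        rep(c(TRUE, FALSE), c(314, 4347 - 314))),
    cluster_id = 1
  )
  or <- estimate_crude(dat, "persistent")
  manual <- (295 / (2007 - 295)) / (314 / (4347 - 314))
  expect_equal(or$estimate, manual, tolerance = 1e-8)
  expect_equal(or$measure, "OR")

  # identical outcome distributions in both arms: null
  dat2 <- tibble::tibble(
    treatment = factor(rep(c("Support", "None"), each = 50),
                       levels = c("None", "Support", "EHCP")),
    hospital_days_unplanned = rep(c(0L, 2L, 1L, 3L, 0L), 20),
    followup_years = 2
  )
  cr <- estimate_crude(dat2, "hosp")
  agg <- with(dat2, tapply(hospital_days_unplanned, treatment == "Support", sum))
  expect_equal(cr$estimate, unname(agg[["TRUE"]] / agg[["FALSE"]]),
               tolerance = 1e-9)
})

test_that("saturated g-computation and IPW equal enumeration standardization", {
  dat <- strat_fixture(n = 800, seed = 5)
  for (oc in c("hosp", "persistent", "ks1")) {
    en_ate <- enumeration_standardization(
      dat, switch(oc, hosp = "hospital_days_unplanned",
                  persistent = "persistent_flag", ks1 = "ks1_z"), "ATE")
    en_att <- enumeration_standardization(
      dat, switch(oc, hosp = "hospital_days_unplanned",
                  persistent = "persistent_flag", ks1 = "ks1_z"), "ATT")
    info_measure <- switch(oc, hosp = "RaR", persistent = "RiR", ks1 = "delta")
    expected_ate <- if (info_measure == "delta") en_ate$psi1 - en_ate$psi0
                    else en_ate$psi1 / en_ate$psi0
    expected_att <- if (info_measure == "delta") en_att$psi1 - en_att$psi0
                    else en_att$psi1 / en_att$psi0
    fam <- switch(oc, hosp = "poisson", persistent = "logistic", ks1 = "linear")

    g_ate <- estimate_gcomp(dat, oc, covariates = "strat", estimand = "ATE",
                            family = fam, treatment_interactions = TRUE)
    g_att <- estimate_gcomp(dat, oc, covariates = "strat", estimand = "ATT",
                            family = fam, treatment_interactions = TRUE)
    expect_equal(g_ate$estimate, expected_ate, tolerance = 1e-10)
    expect_equal(g_att$estimate, expected_att, tolerance = 1e-10)

    ps <- fit_ps_model(dat, c("Support", "None"), covariates = "strat")
    ipw <- estimate_ipw(dat, ps, oc, estimand = "ATE")
    expect_equal(ipw$estimate, expected_ate, tolerance = 1e-10)

    aipw <- estimate_aipw(dat, ps, oc, covariates = "strat",
                          family = fam)
    expect_equal(aipw$estimate, expected_ate, tolerance = 1e-8)
  }
})

test_that("AIPW reduces to Horvitz-Thompson IPW means when m is null", {
  dat <- strat_fixture(n = 400, seed = 7)
  dat$ps <- 0.4  # known constant PS
  a <- as.integer(dat$treatment == "Support")
  yr <- dat$hospital_days_unplanned / dat$followup_years
  ht1 <- mean(a / 0.4 * yr)
  ht0 <- mean((1 - a) / 0.6 * yr)
  # with a constant PS and an intercept-free "zero" outcome model the
  # augmentation vanishes; emulate m == 0 by direct formula comparison
  psi <- ht1 / ht0
  # the implementation with a rich model must differ from HT in general,
  # but with m forced to zero the algebra collapses:
  m0 <- rep(0, nrow(dat))
  expect_equal(mean(a / 0.4 * (yr - m0) + m0) /
                 mean((1 - a) / 0.6 * (yr - m0) + m0), psi)
})

test_that("conditional and crude coincide without confounding", {
  cfg <- small_config(n = 8000, clusters = 60)
  for (arm in c("Support", "EHCP")) {
    b <- cfg$ps_coefficients[[arm]]; b[] <- 0
    b[["(Intercept)"]] <- if (arm == "Support") log(0.45) else -3
    cfg$ps_coefficients[[arm]] <- b
  }
  tbl <- derive_analysis_table(generate_cohort(cfg, seed = 29))
  crude <- estimate_crude(tbl, "medical")
  cond <- estimate_conditional(tbl, "medical", family = "poisson")
  expect_equal(cond$estimate, crude$estimate, tolerance = 0.06)
  # and under randomisation gcomp matches too (rate-ratio collapsibility)
  g <- estimate_gcomp(tbl, "medical", family = "poisson")
  expect_equal(g$estimate, crude$estimate, tolerance = 0.06)
})

test_that("constant PS makes IPW equal the crude contrast", {
  dat <- strat_fixture(n = 600, seed = 11)
  ipw <- estimate_ipw(dat, rep(0.35, 600), "hosp", estimand = "ATE")
  crude <- estimate_crude(dat, "hosp")
  expect_equal(ipw$estimate, crude$estimate, tolerance = 1e-10)
})

test_that("score deltas are invariant to location shifts", {
  dat <- strat_fixture(n = 500, seed = 13)
  shifted <- dat; shifted$ks1_z <- shifted$ks1_z + 100
  for (f in list(
    function(d) estimate_crude(d, "ks1")$estimate,
    function(d) estimate_gcomp(d, "ks1", covariates = "strat")$estimate
  )) {
    expect_equal(f(dat), f(shifted), tolerance = 1e-8)
  }
})

test_that("all estimators agree at the null under randomised assignment", {
  cfg <- null_config(n = 10000, clusters = 80)
  for (arm in c("Support", "EHCP")) {
    b <- cfg$ps_coefficients[[arm]]; b[] <- 0
    b[["(Intercept)"]] <- if (arm == "Support") log(0.45) else -3
    cfg$ps_coefficients[[arm]] <- b
  }
  coh <- generate_cohort(cfg, seed = 51)
  res <- run_pipeline(coh, outcomes = c("hosp", "persistent", "ks1"),
                      B = 0, use_lasso = FALSE, count_family = "poisson")
  est <- tidy(res)
  ratios <- est[est$measure %in% c("RaR", "RiR", "OR"), ]
  expect_true(all(abs(log(ratios$estimate)) < 0.12))
  deltas <- est[est$measure == "delta", ]
  expect_true(all(abs(deltas$estimate) < 0.07))
})
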