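arm_fixture <- function(n0, n1) {
  tibble::tibble(
    treatment = factor(rep(c("None", "Support"), c(n0, n1)),
                       levels = c("None", "Support", "EHCP")),
    cluster_id = rep(1:10, length.out = n0 + n1)
  )
}

test_that("intercept-only PS equals the exposed-arm fraction", {
  dat <- arm_fixture(4350, 2009)
  fit <- fit_ps_model(dat, c("Support", "None"), covariates = character(0))
  expect_equal(unique(round(fit$data$ps, 6)), round(2009 / 6359, 6))
  expect_equal(mean(fit$data$ps), 2009 / 6359, tolerance = 1e-9)
})

test_that("saturated PS on a binary covariate recovers stratum fractions", {
  set.seed(2)
  n <- 600
  x <- factor(rbinom(n, 1, 0.5))
  a <- rbinom(n, 1, ifelse(x == "1", 0.6, 0.2))
  dat <- tibble::tibble(
    treatment = factor(ifelse(a == 1, "Support", "None"),
                       levels = c("None", "Support", "EHCP")),
    xf = x, cluster_id = 1
  )
  fit <- fit_ps_model(dat, c("Support", "None"), covariates = "xf")
  for (lv in levels(x)) {
    emp <- mean(a[x == lv])
    expect_equal(unique(round(fit$data$ps[dat$xf == lv], 8)), round(emp, 8))
  }
})

test_that("mean fitted PS equals exposed fraction (score equation)", {
  coh <- generate_cohort(small_config(n = 4000, clusters = 50), seed = 23)
  tbl <- derive_analysis_table(coh)
  fit <- fit_ps_model(tbl, c("Support", "None"))
  expect_equal(mean(fit$data$ps), mean(fit$data$.a), tolerance = 1e-8)
})

test_that("fitted PS recovers the generating assignment law", {
  coh <- generate_cohort(cohort_config(n_pupils = 20000, n_clusters = 100),
                         seed = 31, apply_missingness = FALSE)
  tbl <- derive_analysis_table(coh)
  fit <- fit_ps_model(tbl, c("Support", "None"))
  expect_gt(cor(fit$data$ps, fit$data$true_ps_support), 0.95)
})

test_that("ATE weighting balances modelled covariates", {
  coh <- generate_cohort(cohort_config(n_pupils = 20000, n_clusters = 100),
                         seed = 37)
  tbl <- derive_analysis_table(coh)
  fit <- fit_ps_model(tbl, c("Support", "None"))
  d <- fit$data
  w <- ipw_weights(d$ps, d$.a, "ATE")$w
  smd <- function(x) {
    m1 <- weighted.mean(x[d$.a == 1], w[d$.a == 1])
    m0 <- weighted.mean(x[d$.a == 0], w[d$.a == 0])
    s <- sqrt((var(x[d$.a == 1]) + var(x[d$.a == 0])) / 2)
    abs(m1 - m0) / s
  }
  checks <- c("eyfsp_z", "prior_hosp_rate", "school_sen_prop",
              "relative_age", "school_fsm_prop")
  for (v in checks) expect_lt(smd(d[[v]]), 0.05)
  expect_lt(smd(as.numeric(d$fsm == "Eligible")), 0.05)
  expect_lt(smd(d$chronic_any), 0.05)
})

test_that("overlap summary and positivity gate behave on known patterns", {
  # both arms everywhere
  dat <- tibble::tibble(ps = rep(seq(0.1, 0.9, length.out = 100), 2),
                        .a = rep(c(0L, 1L), each = 100))
  ov <- overlap_summary(dat)
  expect_equal(positivity_check(ov$table), "pass")
  # top decile exposed-only
  set.seed(12)
  dat2 <- tibble::tibble(
    ps = c(runif(260, 0.05, 0.5), runif(100, 0.05, 0.5), runif(60, 0.9, 0.99)),
    .a = c(rep(0L, 260), rep(1L, 160))
  )
  ov2 <- overlap_summary(dat2)
  expect_equal(positivity_check(ov2$table), "fail")
  # sparse but two-sided: warn
  expect_equal(positivity_check(
    tibble::tibble(exposed = c(10, 2), reference = c(10, 10))), "warn")
})

test_that("positivity flags reproduce the analysed / refused contrasts", {
  coh <- generate_cohort(cohort_config(), seed = 41)
  tbl <- derive_analysis_table(coh)
  fitSN <- fit_ps_model(tbl, c("Support", "None"))
  expect_equal(fitSN$flag, "pass")
  fitEN <- fit_ps_model(tbl, c("EHCP", "None"))
  expect_equal(fitEN$flag, "fail")
  # the EHCP-like contrast concentrates reference mass near zero
  expect_lt(median(fitEN$data$ps[fitEN$data$.a == 0]), 0.05)
})

test_that("lasso keeps signal covariates and drops pure noise", {
  hits <- 0; seeds <- 1:10
  for (s in seeds) {
    set.seed(s)
    n <- 4000
    X <- matrix(rnorm(n * 13), n, 13,
                dimnames = list(NULL, paste0("x", 1:13)))
    y <- 1.0 * X[, 1] - 0.8 * X[, 2] + 0.6 * X[, 3] + rnorm(n)
    sel <- lasso_select(X, y, family = "gaussian", seed = s)
    if (all(c("x1", "x2", "x3") %in% sel)) hits <- hits + 1
  }
  expect_gte(hits, 8)
  # forced terms survive even under heavy penalisation
  set.seed(1)
  X <- matrix(rnorm(2000), 500, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rnorm(500)  # no signal at all
  sel <- lasso_select(X, y, force = "x4", seed = 1)
  expect_true("x4" %in% sel)
})
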