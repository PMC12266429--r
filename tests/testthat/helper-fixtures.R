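# shared fixtures, all built in code

# default generating law at reduced size
small_config <- function(n = 2000, clusters = 40, ...) {
  cohort_config(n_pupils = n, n_clusters = clusters, ...)
}

# default law with all treatment effects removed (confounding retained)
null_config <- function(n = 6601, clusters = 150) {
  cfg <- cohort_config(n_pupils = n, n_clusters = clusters)
  for (nm in names(cfg$outcome_specs)) {
    cfg$outcome_specs[[nm]]$effects[] <- 0
  }
  cfg
}

# law in which assignment depends on a handful of covariates only, so an
# analysis adjusting for exactly those covariates is correctly specified
few_confounder_config <- function(n = 1500, clusters = 75) {
  cfg <- cohort_config(n_pupils = n, n_clusters = clusters)
  for (arm in c("Support", "EHCP")) {
    b <- cfg$ps_coefficients[[arm]]
    keep <- c("(Intercept)", "fsmEligible", "chronic_any", "eyfsp_z",
              "cleft_typeLipOnly", "cleft_typeUnilateral", "cleft_typeBilateral")
    b[setdiff(names(b), keep)] <- 0
    cfg$ps_coefficients[[arm]] <- b
  }
  cfg
}
few_confounder_covariates <- c("fsm", "chronic_any", "eyfsp_z", "cleft_type")

# discrete-stratum analysis fixture: two binary covariates (4 strata),
# unit follow-up, Poisson-ish counts, a binary flag and a score, with
# assignment probabilities depending on the stratum
strat_fixture <- function(n = 800, seed = 5) {
  set.seed(seed)
  x1 <- rbinom(n, 1, 0.4)
  x2 <- rbinom(n, 1, 0.5)
  p <- plogis(-0.8 + 1.1 * x1 + 0.6 * x2)
  a <- rbinom(n, 1, p)
  lam <- exp(0.2 + 0.5 * x1 - 0.3 * x2 + 0.4 * a)
  y <- rpois(n, lam)
  flag <- rbinom(n, 1, plogis(-1 + 0.8 * x1 + 0.5 * a)) == 1
  score <- 0.3 * x1 - 0.2 * x2 - 0.25 * a + rnorm(n)
  tibble::tibble(
    pupil_id = seq_len(n),
    cluster_id = rep(1:20, length.out = n),
    treatment = factor(ifelse(a == 1, "Support", "None"),
                       levels = c("None", "Support", "EHCP")),
    strat = factor(paste0(x1, x2)),
    x1 = x1, x2 = x2,
    hospital_days_unplanned = y,
    followup_years = 1,
    persistent_flag = flag,
    ks1_z = score
  )
}

# exact nonparametric standardization over discrete strata (enumeration
# oracle, independent of the model-based estimators)
enumeration_standardization <- function(dat, outcome_col, estimand = "ATE") {
  pop <- if (estimand == "ATE") dat else dat[dat$treatment == "Support", ]
  ws <- table(pop$strat) / nrow(pop)
  m <- function(arm) {
    sapply(names(ws), function(s) {
      mean(dat[[outcome_col]][dat$strat == s & dat$treatment == arm])
    })
  }
  list(psi1 = sum(ws * m("Support")), psi0 = sum(ws * m("None")))
}
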