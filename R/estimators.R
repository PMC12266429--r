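#' Registry of analysis outcomes
#'
#' Maps each analysis outcome to its column, exposure denominator,
#' default model family and effect measure. Count outcomes are reported
#' as rate ratios (RaR), the persistent-absence flag as a risk ratio
#' (RiR; odds ratio for the crude row, following the usual report
#' layout), and attainment scores as mean differences (delta).
#'
#' @return A tibble with one row per outcome.
#' @export
analysis_outcomes <- function() {
  tibble::tribble(
    ~outcome,      ~var,                        ~exposure,           ~family,    ~measure,
    "hosp",        "hospital_days_unplanned",   "followup_years",    "negbin",   "RaR",
    "hosp_ae",     "hospital_days_ae",          "followup_years",    "negbin",   "RaR",
    "hosp_apc",    "hospital_days_apc",         "followup_years",    "negbin",   "RaR",
    "medical",     "sessions_medical",          "sessions_possible", "negbin",   "RaR",
    "unauth",      "sessions_unauth",           "sessions_possible", "negbin",   "RaR",
    "persistent",  "persistent_flag",           NA,                  "logistic", "RiR",
    "ks1",         "ks1_z",                     NA,                  "linear",   "delta",
    "ks2",         "ks2_z",                     NA,                  "linear",   "delta",
    "progress_ks1", "progress_ks1",             NA,                  "linear",   "delta",
    "progress_ks2", "progress_ks2",             NA,                  "linear",   "delta"
  )
}

outcome_info <- function(outcome) {
  reg <- analysis_outcomes()
  row <- reg[reg$outcome == outcome, ]
  if (nrow(row) != 1) stop("unknown outcome: ", outcome, call. = FALSE)
  as.list(row)
}

# rows usable for an outcome: non-missing response, positive exposure
outcome_frame <- function(dat, info) {
  y <- dat[[info$var]]
  keep <- !is.na(y)
  if (!is.na(info$exposure)) keep <- keep & dat[[info$exposure]] > 0
  dat <- dat[keep, , drop = FALSE]
  dat$.y <- as.numeric(dat[[info$var]])
  dat$.exposure <- if (!is.na(info$exposure)) dat[[info$exposure]] else rep(1, nrow(dat))
  dat
}

effect_row <- function(outcome, contrast, estimand, estimator, measure,
                       point, n, diagnostics = list()) {
  out <- tibble::tibble(
    outcome = outcome, contrast = paste(contrast[1], "vs", contrast[2]),
    estimand = estimand, estimator = estimator, measure = measure,
    estimate = point, ci_low = NA_real_, ci_high = NA_real_, n = n,
    diagnostics = list(diagnostics)
  )
  class(out) <- c("effect_estimate", class(out))
  out
}

#' Inverse-probability weights for ATE or ATT
#'
#' ATE: exposed pupils weighted `1/ps`, reference pupils `1/(1-ps)`.
#' ATT: exposed weight 1, reference `ps/(1-ps)`.
#'
#' @param ps Propensity of the exposed level, strictly inside (0,1).
#' @param treatment_indicator 1 = exposed, 0 = reference.
#' @param estimand `"ATE"` or `"ATT"`.
#' @return List of class `weight_set`: `w` (weights), `estimand`,
#'   `summary` (max weight and Kish effective sample size).
#' @examples
#' ipw_weights(c(0.5, 0.25), c(0, 1), "ATE")$w  # 2, 4
#' @export
ipw_weights <- function(ps, treatment_indicator, estimand = c("ATE", "ATT")) {
  estimand <- match.arg(estimand)
  if (any(ps <= 0 | ps >= 1)) {
    stop("propensity scores at 0 or 1: positivity violation", call. = FALSE)
  }
  a <- treatment_indicator
  w <- if (estimand == "ATE") ifelse(a == 1, 1 / ps, 1 / (1 - ps))
       else ifelse(a == 1, 1, ps / (1 - ps))
  structure(list(
    w = w, estimand = estimand,
    summary = c(max = max(w), ess = sum(w)^2 / sum(w^2))
  ), class = "weight_set")
}

#' Fit an outcome regression model
#'
#' Dispatches to the family a practitioner would use: negative binomial
#' (`MASS::glm.nb`, dispersion estimated by ML) or Poisson with a
#' log-exposure offset for counts, logistic for binary outcomes, linear
#' for scores. If the negative-binomial dispersion estimate diverges
#' (no overdispersion), the fit falls back to Poisson with a warning.
#'
#' @param data Analysis tibble (rows already restricted to the contrast).
#' @param outcome Response column name.
#' @param family `"negbin"`, `"poisson"`, `"logistic"` or `"linear"`.
#' @param covariates RHS terms (include `".a"` for the treatment
#'   indicator); empty for intercept-only.
#' @param offset Exposure column name (count families), or `NULL`.
#' @param weights Optional prior weights.
#' @param quadratic Covariates also entered squared.
#' @param treatment_interactions Interact the treatment indicator `.a`
#'   with every covariate (a saturated model when the covariates are one
#'   stratum factor).
#' @return The fitted model object (attribute `family_used`).
#' @export
fit_outcome_model <- function(data, outcome, family, covariates = ".a",
                              offset = NULL, weights = NULL,
                              quadratic = character(),
                              treatment_interactions = FALSE) {
  stopifnot(family %in% c("negbin", "poisson", "logistic", "linear"))
  rhs <- if (length(covariates) == 0) "1" else build_rhs(covariates, quadratic)
  if (treatment_interactions && ".a" %in% covariates) {
    rest <- setdiff(covariates, ".a")
    rhs <- if (length(rest) == 0) ".a" else
      paste0(".a * (", build_rhs(rest, quadratic), ")")
  }
  off_str <- if (!is.null(offset)) paste0(" + offset(log(`", offset, "`))") else ""
  fml <- as.formula(paste0("`", outcome, "` ~ ", rhs,
                           if (family %in% c("negbin", "poisson")) off_str else ""))
  data$.w <- if (is.null(weights)) rep(1, nrow(data)) else weights
  fit <- switch(family,
    linear = lm(fml, data = data, weights = .w),
    logistic = glm(fml, data = data, weights = .w,
                   family = if (is.null(weights)) binomial() else quasibinomial(),
                   control = list(epsilon = 1e-12, maxit = 100)),
    poisson = glm(fml, data = data, weights = .w, family = poisson(),
                  control = list(epsilon = 1e-12, maxit = 100)),
    negbin = tryCatch(
      suppressWarnings(MASS::glm.nb(fml, data = data, weights = .w,
                                    control = stats::glm.control(epsilon = 1e-10,
                                                                 maxit = 100))),
      error = function(e) {
        warning("negative-binomial dispersion did not converge (",
                conditionMessage(e), "); falling back to Poisson",
                call. = FALSE)
        glm(fml, data = data, weights = .w, family = poisson(),
            control = list(epsilon = 1e-12, maxit = 100))
      })
  )
  if (family == "negbin" && inherits(fit, "negbin") && fit$theta > 1e5) {
    warning("no overdispersion detected; negative binomial ~ Poisson limit",
            call. = FALSE)
  }
  attr(fit, "family_used") <- if (inherits(fit, "negbin")) "negbin" else family
  fit
}

treatment_coef_measure <- function(info, crude = FALSE) {
  if (info$family == "logistic") return("OR")
  if (info$measure == "delta") return("delta")
  "RaR"
}

coef_estimate <- function(fit, info) {
  b <- coef(fit)[[".a"]]
  if (info$measure == "delta") b else exp(b)
}

#' Crude (unadjusted) association
#'
#' Treatment-only model of the outcome family on the two contrast arms:
#' Poisson with log-exposure offset for counts (the exponentiated
#' coefficient equals the ratio of aggregate rates), logistic (odds
#' ratio) for the persistent-absence flag, linear for scores.
#'
#' @param table Analysis tibble.
#' @param outcome Outcome name (see [analysis_outcomes()]).
#' @param contrast `c(exposed, reference)`.
#' @return One-row effect tibble.
#' @export
estimate_crude <- function(table, outcome, contrast = c("Support", "None")) {
  info <- outcome_info(outcome)
  dat <- outcome_frame(restrict_contrast(table, contrast), info)
  fam <- switch(info$family, negbin = "poisson", info$family)
  fit <- fit_outcome_model(dat, ".y", fam, covariates = ".a",
                           offset = if (!is.na(info$exposure)) ".exposure")
  effect_row(outcome, contrast, "crude", "regression",
             treatment_coef_measure(info, crude = TRUE),
             coef_estimate(fit, info), nrow(dat))
}

#' Conditional association (multivariable regression)
#'
#' Full-covariate (MCIM design) model of the outcome family; the
#' treatment coefficient is reported on the outcome scale (rate ratio,
#' odds ratio, or mean difference).
#'
#' @inheritParams estimate_crude
#' @param covariates Adjustment terms (default: MCIM confounder set).
#' @param family Override the registry family (e.g. `"poisson"`).
#' @return One-row effect tibble.
#' @export
estimate_conditional <- function(table, outcome,
                                 contrast = c("Support", "None"),
                                 covariates = NULL, family = NULL) {
  info <- outcome_info(outcome)
  table <- apply_mcim(table)
  if (is.null(covariates)) covariates <- attr(table, "mcim_terms")
  dat <- outcome_frame(restrict_contrast(table, contrast), info)
  fit <- fit_outcome_model(dat, ".y", family %||% info$family,
                           covariates = c(".a", covariates),
                           offset = if (!is.na(info$exposure)) ".exposure")
  effect_row(outcome, contrast, "conditional", "regression",
             treatment_coef_measure(info), coef_estimate(fit, info), nrow(dat))
}

#' IPW estimate of the ATE or ATT
#'
#' Re-weights each arm by the inverse assignment probability and contrasts
#' weighted marginal outcomes: for counts the ratio of weighted aggregate
#' rates (equal to the weighted treatment-only log-link coefficient), for
#' the binary flag the ratio of weighted outcome means (risk ratio, not
#' odds ratio), for scores the weighted mean difference.
#'
#' @param table Analysis tibble.
#' @param ps A `ps_fit` (from [fit_ps_model()]) or a numeric vector of
#'   propensities aligned with the contrast-restricted rows.
#' @param outcome Outcome name.
#' @param contrast `c(exposed, reference)`.
#' @param estimand `"ATE"` or `"ATT"`.
#' @param weight_cap Diagnostics-only threshold: a maximum weight above
#'   it is recorded as a warning in the diagnostics.
#' @return One-row effect tibble.
#' @export
estimate_ipw <- function(table, ps, outcome, contrast = c("Support", "None"),
                         estimand = c("ATE", "ATT"), weight_cap = 50) {
  estimand <- match.arg(estimand)
  info <- outcome_info(outcome)
  dat <- if (inherits(ps, "ps_fit")) ps$data else {
    d <- restrict_contrast(table, contrast); d$ps <- ps; d
  }
  dat <- outcome_frame(dat, info)
  ws <- ipw_weights(dat$ps, dat$.a, estimand)
  w <- ws$w; a <- dat$.a
  point <- if (info$measure == "RaR") {
    (sum(w[a == 1] * dat$.y[a == 1]) / sum(w[a == 1] * dat$.exposure[a == 1])) /
      (sum(w[a == 0] * dat$.y[a == 0]) / sum(w[a == 0] * dat$.exposure[a == 0]))
  } else if (info$measure == "RiR") {
    weighted.mean(dat$.y[a == 1], w[a == 1]) /
      weighted.mean(dat$.y[a == 0], w[a == 0])
  } else {
    weighted.mean(dat$.y[a == 1], w[a == 1]) -
      weighted.mean(dat$.y[a == 0], w[a == 0])
  }
  diag <- list(max_weight = unname(ws$summary["max"]),
               ess = unname(ws$summary["ess"]))
  if (ws$summary["max"] > weight_cap) {
    diag$warning <- paste0("maximum weight ", round(ws$summary["max"], 1),
                           " exceeds cap ", weight_cap)
  }
  effect_row(outcome, contrast, estimand, "IPW", info$measure, point,
             nrow(dat), diag)
}

#' G-computation (outcome-model standardisation)
#'
#' Fits the outcome model on covariates plus treatment, predicts each
#' pupil's expected outcome under both arms, and averages over the
#' estimand population (all pupils for the ATE; exposed pupils for the
#' ATT). Count predictions are standardised as exposure-weighted marginal
#' rates (total expected events over total exposure) by default.
#'
#' @inheritParams estimate_ipw
#' @param covariates Outcome-model terms (default MCIM confounder set).
#' @param family Override the registry family.
#' @param convention `"aggregate"` (exposure-weighted marginal rates) or
#'   `"pupil"` (mean of pupil-level predicted rates) for count ratios.
#' @param treatment_interactions Saturate the outcome model with
#'   treatment-by-covariate interactions (see [fit_outcome_model()]).
#' @return One-row effect tibble.
#' @export
estimate_gcomp <- function(table, outcome, contrast = c("Support", "None"),
                           covariates = NULL, estimand = c("ATE", "ATT"),
                           family = NULL,
                           convention = c("aggregate", "pupil"),
                           treatment_interactions = FALSE) {
  estimand <- match.arg(estimand)
  convention <- match.arg(convention)
  info <- outcome_info(outcome)
  table <- apply_mcim(table)
  if (is.null(covariates)) covariates <- attr(table, "mcim_terms")
  dat <- outcome_frame(restrict_contrast(table, contrast), info)
  fit <- fit_outcome_model(dat, ".y", family %||% info$family,
                           covariates = c(".a", covariates),
                           offset = if (!is.na(info$exposure)) ".exposure",
                           treatment_interactions = treatment_interactions)
  pop <- if (estimand == "ATE") dat else dat[dat$.a == 1, , drop = FALSE]
  pr <- function(a) {
    nd <- pop; nd$.a <- a
    mu <- predict(fit, newdata = nd, type = "response")
    if (info$measure == "RaR") mu / pop$.exposure else mu
  }
  r1 <- pr(1L); r0 <- pr(0L)
  point <- if (info$measure == "RaR" && convention == "aggregate") {
    sum(r1 * pop$.exposure) / sum(r0 * pop$.exposure)
  } else if (info$measure == "delta") {
    mean(r1) - mean(r0)
  } else {
    mean(r1) / mean(r0)
  }
  effect_row(outcome, contrast, estimand, "gcomp", info$measure, point,
             nrow(dat), list(family = attr(fit, "family_used")))
}

#' Augmented IPW (doubly robust) estimate
#'
#' For each arm `a`, the counterfactual mean is the augmented mean
#' `psi_a = mean[ I(A=a)/p_a(X) (Y - m_a(X)) + m_a(X) ]` on the rate
#' scale for counts (observed count over exposure; predicted rate),
#' probability scale for the binary flag, raw scale for scores. The
#' estimate is `psi_exposed / psi_reference` (ratios) or their
#' difference. Consistent if either the propensity model or the outcome
#' model is correctly specified. Count outcome models default to Poisson.
#' The ATT uses the standard ATT estimating equations (reference-arm
#' residuals weighted by `p/(1-p)`, normalised); it is an extension where
#' reference reports leave the cell blank.
#'
#' @inheritParams estimate_gcomp
#' @param ps A `ps_fit` or aligned propensity vector.
#' @param eps Positivity guard: error if any `ps` lies outside
#'   `(eps, 1-eps)`.
#' @return One-row effect tibble.
#' @export
estimate_aipw <- function(table, ps, outcome, contrast = c("Support", "None"),
                          covariates = NULL, estimand = c("ATE", "ATT"),
                          family = NULL, eps = 1e-6,
                          treatment_interactions = FALSE) {
  estimand <- match.arg(estimand)
  info <- outcome_info(outcome)
  table <- apply_mcim(table)
  if (is.null(covariates)) covariates <- attr(table, "mcim_terms")
  dat <- if (inherits(ps, "ps_fit")) ps$data else {
    d <- restrict_contrast(table, contrast); d$ps <- ps; d
  }
  if (is.null(attr(dat, "mcim_terms"))) dat <- apply_mcim(dat)
  dat <- outcome_frame(dat, info)
  if (any(dat$ps < eps | dat$ps > 1 - eps)) {
    stop("propensity scores outside (eps, 1-eps): positivity violation",
         call. = FALSE)
  }
  fam <- family %||% switch(info$family, negbin = "poisson", info$family)
  fit <- fit_outcome_model(dat, ".y", fam, covariates = c(".a", covariates),
                           offset = if (!is.na(info$exposure)) ".exposure",
                           treatment_interactions = treatment_interactions)
  m <- function(a) {
    nd <- dat; nd$.a <- a
    mu <- predict(fit, newdata = nd, type = "response")
    if (info$measure == "RaR") mu / dat$.exposure else mu
  }
  yr <- if (info$measure == "RaR") dat$.y / dat$.exposure else dat$.y
  a <- dat$.a; p <- dat$ps
  m1 <- m(1L); m0 <- m(0L)
  if (estimand == "ATE") {
    psi1 <- mean(a / p * (yr - m1) + m1)
    psi0 <- mean((1 - a) / (1 - p) * (yr - m0) + m0)
  } else {
    n1 <- sum(a)
    psi1 <- sum(a * yr) / n1
    wr <- (1 - a) * p / (1 - p)
    psi0 <- sum(a * m0) / n1 + sum(wr * (yr - m0)) / sum(wr)
  }
  point <- if (info$measure == "delta") psi1 - psi0 else psi1 / psi0
  effect_row(outcome, contrast, estimand, "AIPW", info$measure, point,
             nrow(dat),
             list(family = attr(fit, "family_used"),
                  att_extension = estimand == "ATT"))
}
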