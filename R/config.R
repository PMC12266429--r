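#' Configuration for the synthetic clustered cohort generator
#'
#' Builds a validated configuration object describing the data-generating
#' law of a synthetic pupil cohort: confounder marginals, the
#' multinomial-logit treatment-assignment law over the three SEN provision
#' levels (None / Support / EHCP), per-outcome generating families with
#' cluster random intercepts, and the missing-at-random masking law for
#' covariates with "Unknown" levels.
#'
#' The defaults describe a cohort of 6,601 pupils in 150 local-authority
#' clusters with treatment prevalences near 66/30/4 percent, overdispersed
#' count outcomes with person-time or session offsets, year-standardised
#' attainment scores, and MAR missingness concentrated in birth
#' characteristics.
#'
#' @param n_pupils Number of pupils to generate.
#' @param n_clusters Number of local-authority clusters (each pupil belongs
#'   to exactly one).
#' @param ps_coefficients Named list with elements `Support` and `EHCP`,
#'   each a named numeric vector of log-odds coefficients (versus `None`)
#'   on the generator design; names not supplied default to zero.
#' @param outcome_specs Named list of outcome generating specifications,
#'   see [default_outcome_specs()].
#' @param missingness Named list of MAR masking laws, see
#'   [default_missingness()].
#' @param covariates Confounder marginal distributions, see
#'   [default_covariate_marginals()].
#' @param persistent_mode `"derived"` (default): the persistent-absence flag
#'   is the deterministic >= 10 percent functional of simulated absence
#'   sessions. `"logistic"`: an independent direct logistic draw (for power
#'   experiments), using the `persistent` outcome spec.
#' @param overlap_prob Probability that a day with both an A&E visit and an
#'   admission is counted once (same-day deduplication intensity).
#' @param sessions_per_year Expected possible half-day school sessions per
#'   followed year.
#' @param score_sit_prob Probability that a pupil who reached the relevant
#'   school year actually sat each key-stage assessment.
#'
#' @return An object of class `cohort_config` (a list).
#' @seealso [generate_cohort()], [true_marginal_effects()]
#' @examples
#' cfg <- cohort_config(n_pupils = 500, n_clusters = 20)
#' cfg$ps_coefficients$Support[["(Intercept)"]]
#' @export
cohort_config <- function(n_pupils = 6601,
                          n_clusters = 150,
                          ps_coefficients = default_ps_coefficients(),
                          outcome_specs = default_outcome_specs(),
                          missingness = default_missingness(),
                          covariates = default_covariate_marginals(),
                          persistent_mode = c("derived", "logistic"),
                          overlap_prob = 0.25,
                          sessions_per_year = 325,
                          score_sit_prob = 0.97) {
  persistent_mode <- match.arg(persistent_mode)
  stopifnot(
    is.numeric(n_pupils), length(n_pupils) == 1, n_pupils >= 1,
    is.numeric(n_clusters), length(n_clusters) == 1, n_clusters >= 1,
    n_clusters <= n_pupils,
    overlap_prob >= 0, overlap_prob <= 1,
    sessions_per_year > 0
  )
  design_names <- generator_design_names(covariates)
  ps_coefficients <- lapply(ps_coefficients, complete_coef, design_names)
  if (!setequal(names(ps_coefficients), c("Support", "EHCP"))) {
    stop("`ps_coefficients` must have elements 'Support' and 'EHCP'", call. = FALSE)
  }
  outcome_specs <- lapply(outcome_specs, validate_outcome_spec, design_names)
  for (nm in names(missingness)) {
    if (!nm %in% c(names(covariates$categorical), names(covariates$continuous))) {
      stop("missingness spec refers to unknown covariate: ", nm, call. = FALSE)
    }
  }
  structure(
    list(
      n_pupils = as.integer(n_pupils),
      n_clusters = as.integer(n_clusters),
      treatment_levels = c("None", "Support", "EHCP"),
      ps_coefficients = ps_coefficients,
      outcome_specs = outcome_specs,
      missingness = missingness,
      covariates = covariates,
      persistent_mode = persistent_mode,
      overlap_prob = overlap_prob,
      sessions_per_year = sessions_per_year,
      score_sit_prob = score_sit_prob
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  pupils:", x$n_pupils, " clusters:", x$n_clusters, "\n")
  cat("  outcomes:", paste(names(x$outcome_specs), collapse = ", "), "\n")
  cat("  persistent-absence mode:", x$persistent_mode, "\n")
  invisible(x)
}

# fill unnamed design terms with zero; error on unknown names
complete_coef <- function(coef, design_names) {
  if (is.null(names(coef)) && length(coef) > 0) {
    stop("coefficient vectors must be named", call. = FALSE)
  }
  unknown <- setdiff(names(coef), design_names)
  if (length(unknown) > 0) {
    stop("unknown design term(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- setNames(numeric(length(design_names)), design_names)
  out[names(coef)] <- coef
  out
}

validate_outcome_spec <- function(spec, design_names) {
  fam <- spec$family
  if (!fam %in% c("negbin", "binary", "normal")) {
    stop("unknown outcome family: ", fam, call. = FALSE)
  }
  spec$coef <- complete_coef(spec$coef %||% numeric(0), design_names)
  spec$effects <- spec$effects %||% c(Support = 0, EHCP = 0)
  stopifnot(all(c("Support", "EHCP") %in% names(spec$effects)))
  spec$cluster_sd <- spec$cluster_sd %||% 0
  stopifnot(spec$cluster_sd >= 0)
  if (fam == "negbin") {
    if (is.null(spec$dispersion) || spec$dispersion <= 0) {
      stop("negbin outcomes need dispersion (theta) > 0", call. = FALSE)
    }
  }
  if (fam == "normal") {
    if (is.null(spec$sd) || spec$sd <= 0) stop("normal outcomes need sd > 0", call. = FALSE)
  }
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confounder marginal distributions for the generator
#'
#' Categorical marginals follow the observed margins of a national cleft
#' lip/palate school cohort (proportions over pupils with known values);
#' continuous confounders use simple parametric families chosen to match
#' reported medians and IQRs approximately. The dependence structure is
#' induced by a small set of latent regressions (deprivation drives free
#' school meals, chronic conditions and school readiness; cleft severity
#' drives chronic conditions and readiness).
#'
#' @return A list with elements `categorical` (named list of probability
#'   vectors) and `continuous` (metadata consumed by [generate_cohort()]).
#' @export
default_covariate_marginals <- function() {
  list(
    categorical = list(
      gender = c(Female = 0.413, Male = 0.587),
      gest_age = c("39+w" = 0.712, "37-38w" = 0.205, "35-36w" = 0.047, "<=34w" = 0.036),
      birthweight = c("2500-3499g" = 0.533, "3500g+" = 0.376, "<2500g" = 0.091),
      maternal_age = c("25-29" = 0.276, "30-34" = 0.262, "20-24" = 0.211,
                       "35+" = 0.177, "<20" = 0.073),
      ethnicity = c(White = 0.834, Other = 0.166),
      language = c(English = 0.871, Other = 0.129),
      idaci = c(q1_most = 0.264, q2 = 0.217, q3 = 0.194, q4 = 0.171, q5_least = 0.154),
      fsm = c(NotEligible = 0.803, Eligible = 0.197),
      academic_year = setNames(
        c(501, 550, 552, 568, 596, 622, 558, 639, 665, 654, 696) / 6601,
        paste0("y", 1:11)
      ),
      cleft_type = c(PalateOnly = 0.437, Unilateral = 0.250, LipOnly = 0.247,
                     Bilateral = 0.066)
    ),
    # specific chronic-condition flags; chronic_any derived as union with an
    # "other chronic" remainder so the any-condition margin is ~42.5%
    chronic = c(chronic_blood = 0.0195, chronic_mental = 0.0385,
                chronic_endo = 0.064, chronic_nonspec = 0.068,
                chronic_other = 0.30),
    continuous = list(
      eyfsp_z = list(),          # built from latent regression, see generate_cohort
      relative_age = list(),     # uniform months 0..11 at school entry
      prior_hosp_rate = list(shape = 1.1, mean = 2.0),
      school_sen_prop = list(mean = 0.12, conc = 60),
      school_fsm_prop = list(mean = 0.15, conc = 40)
    ),
    nursery = 0.60
  )
}

# Terms of the generator design matrix (treatment-assignment and outcome
# linear predictors). Categorical covariates enter as treatment-style
# dummies against the first (most common) level; academic year enters as a
# centred linear trend to keep the generating law low-dimensional.
generator_design_names <- function(covariates = default_covariate_marginals()) {
  cat_terms <- unlist(lapply(
    names(covariates$categorical),
    function(v) {
      lv <- names(covariates$categorical[[v]])
      if (v == "academic_year") return(character(0))
      paste0(v, lv[-1])
    }
  ))
  c("(Intercept)", cat_terms, "year_trend",
    names(covariates$chronic)[names(covariates$chronic) != "chronic_other"],
    "chronic_any", "nursery",
    "eyfsp_z", "relative_age", "prior_hosp_rate",
    "school_sen_prop", "school_fsm_prop")
}

#' Default treatment-assignment coefficients
#'
#' Log-odds (versus None) of SEN Support and EHCP on the generator design.
#' Intercepts are calibrated so the marginal arm shares are close to
#' 66/30/4 percent; slopes reproduce the qualitative gradients seen in
#' national data: boys, preterm and low-birthweight births, deprived areas,
#' free-school-meal eligibility, more severe cleft types, chronic
#' conditions and low school-entry attainment all raise the probability of
#' SEN provision, much more steeply for EHCP.
#'
#' @return Named list with numeric vectors `Support` and `EHCP`.
#' @export
default_ps_coefficients <- function() {
  list(
    Support = c(
      "(Intercept)" = -1.52,
      genderMale = 0.30,
      "gest_age37-38w" = 0.22, "gest_age35-36w" = 0.28, "gest_age<=34w" = 0.55,
      "birthweight3500g+" = -0.22, "birthweight<2500g" = 0.35,
      "maternal_age30-34" = -0.12, "maternal_age20-24" = 0.22,
      "maternal_age35+" = -0.08, "maternal_age<20" = 0.40,
      ethnicityOther = 0.10, languageOther = 0.05,
      idaciq2 = -0.20, idaciq3 = -0.38, idaciq4 = -0.55, idaciq5_least = -0.72,
      fsmEligible = 0.55,
      year_trend = -0.045,
      cleft_typeUnilateral = 0.28, cleft_typeLipOnly = -0.45,
      cleft_typeBilateral = 0.42,
      chronic_blood = 0.30, chronic_mental = 1.00, chronic_endo = 0.25,
      chronic_nonspec = 0.75, chronic_any = 0.45,
      nursery = -0.10,
      eyfsp_z = -0.55, relative_age = -0.045, prior_hosp_rate = 0.050,
      school_sen_prop = 1.8, school_fsm_prop = 0.8
    ),
    EHCP = c(
      "(Intercept)" = -5.52,
      genderMale = 0.55,
      "gest_age37-38w" = 0.25, "gest_age35-36w" = 0.30, "gest_age<=34w" = 1.10,
      "birthweight3500g+" = -0.45, "birthweight<2500g" = 0.75,
      "maternal_age30-34" = 0.05, "maternal_age20-24" = -0.05,
      "maternal_age35+" = 0.10, "maternal_age<20" = -0.05,
      ethnicityOther = 0.25, languageOther = 0.15,
      idaciq2 = 0.05, idaciq3 = 0.15, idaciq4 = 0.10, idaciq5_least = 0.15,
      fsmEligible = 0.20,
      year_trend = -0.03,
      cleft_typeUnilateral = 0.05, cleft_typeLipOnly = -0.85,
      cleft_typeBilateral = 0.55,
      chronic_blood = 1.10, chronic_mental = 2.30, chronic_endo = 0.85,
      chronic_nonspec = 1.90, chronic_any = 0.55,
      nursery = -0.05,
      eyfsp_z = -1.30, relative_age = -0.03, prior_hosp_rate = 0.09,
      school_sen_prop = 2.0, school_fsm_prop = 0.6
    )
  )
}

#' Default outcome generating specifications
#'
#' One spec per simulated outcome. Count outcomes (A&E days, admitted days,
#' medical / unauthorised / other-authorised absence sessions) are
#' negative binomial via a shared pupil gamma frailty, with log link and an
#' offset (follow-up years for hospital days; possible sessions for
#' absences). Attainment scores are normal. Treatment effects are on the
#' link scale; baseline rates and dispersions are calibrated so the
#' default cohort reproduces the reported outcome margins (overall
#' unplanned-hospitalisation rate near 385 per 1000 years, medical and
#' unauthorised absence rates near 35 and 10 per 1000 sessions, persistent
#' absence near 10 percent).
#'
#' @return Named list of outcome specs.
#' @export
default_outcome_specs <- function() {
  conf_hosp <- c(
    chronic_any = 0.18, chronic_mental = 0.16, chronic_nonspec = 0.18,
    fsmEligible = 0.11, idaciq5_least = -0.09, "gest_age<=34w" = 0.14,
    cleft_typeLipOnly = -0.11, cleft_typeBilateral = 0.05,
    eyfsp_z = -0.045, prior_hosp_rate = 0.045
  )
  list(
    hosp_ae = list(
      family = "negbin", offset = "followup_years",
      base = -1.757, dispersion = 0.40, cluster_sd = 0.2,
      coef = conf_hosp,
      effects = c(Support = 0, EHCP = 0.30)
    ),
    hosp_apc = list(
      family = "negbin", offset = "followup_years",
      base = -2.299, dispersion = 0.35, cluster_sd = 0.2,
      coef = conf_hosp * 1.2,
      effects = c(Support = log(1.30), EHCP = 0.70)
    ),
    sessions_medical = list(
      family = "negbin", offset = "sessions_possible",
      base = -3.776, dispersion = 2.5, cluster_sd = 0.2,
      coef = c(chronic_any = 0.21, chronic_mental = 0.175, chronic_nonspec = 0.175,
               fsmEligible = 0.084, eyfsp_z = -0.056, prior_hosp_rate = 0.056,
               "gest_age<=34w" = 0.105, cleft_typeLipOnly = -0.07),
      effects = c(Support = log(1.09), EHCP = 0.30)
    ),
    sessions_unauth = list(
      family = "negbin", offset = "sessions_possible",
      base = -4.599, dispersion = 1.2, cluster_sd = 0.2,
      coef = c(fsmEligible = 0.55, idaciq2 = -0.12, idaciq3 = -0.30,
               idaciq4 = -0.45, idaciq5_least = -0.60, "maternal_age<20" = 0.30,
               eyfsp_z = -0.10),
      effects = c(Support = log(0.98), EHCP = 0.10)
    ),
    sessions_other = list(
      family = "negbin", offset = "sessions_possible",
      base = -4.310, dispersion = 3.0, cluster_sd = 0.2,
      coef = c(chronic_any = 0.084, fsmEligible = 0.14, eyfsp_z = -0.035),
      effects = c(Support = 0, EHCP = 0.10)
    ),
    persistent = list(
      # used only in persistent_mode = "logistic"
      family = "binary",
      base = qlogis(0.08), cluster_sd = 0.2,
      coef = c(fsmEligible = 0.8, chronic_any = 0.4, eyfsp_z = -0.2),
      effects = c(Support = 0.1, EHCP = 0.4)
    ),
    ks1 = list(
      family = "normal", sd = 0.80, cluster_sd = 0.1,
      base = 0.23,
      coef = c(eyfsp_z = 0.55, fsmEligible = -0.25, chronic_any = -0.15,
               chronic_mental = -0.30, "gest_age<=34w" = -0.12,
               relative_age = 0.015, school_fsm_prop = -0.5),
      effects = c(Support = -0.21, EHCP = -0.95)
    ),
    ks2 = list(
      family = "normal", sd = 0.90, cluster_sd = 0.1,
      base = 0.27,
      coef = c(eyfsp_z = 0.50, fsmEligible = -0.28, chronic_any = -0.15,
               chronic_mental = -0.35, "gest_age<=34w" = -0.12,
               relative_age = 0.010, school_fsm_prop = -0.5),
      effects = c(Support = -0.27, EHCP = -1.05)
    )
  )
}

#' Default missing-at-random masking laws
#'
#' Each element gives a logistic model for the probability that the named
#' covariate is masked ("Unknown"), as a function of fully observed
#' covariates -- missingness concentrates in birth characteristics and is
#' more common for earlier academic cohorts. `rate` is the target marginal
#' masking probability; the intercept is solved at generation time.
#'
#' @return Named list of masking specs (`rate`, plus named slopes on the
#'   generator design).
#' @export
default_missingness <- function() {
  list(
    gest_age = list(rate = 0.227, slopes = c(year_trend = -0.22, fsmEligible = 0.15)),
    birthweight = list(rate = 0.166, slopes = c(year_trend = -0.22, fsmEligible = 0.15)),
    maternal_age = list(rate = 0.040, slopes = c(year_trend = -0.10)),
    idaci = list(rate = 0.002, slopes = c()),
    eyfsp_z = list(rate = 0.009, slopes = c(year_trend = -0.05))
  )
}
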