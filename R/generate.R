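#' Generate a synthetic clustered pupil cohort
#'
#' Draws a cohort of pupils in local-authority clusters: confounders from
#' the configured marginals (with a realistic dependence structure),
#' treatment from the multinomial-logit assignment law, follow-up from the
#' academic-cohort calendar (later entry cohorts are administratively
#' censored before Year 6), and outcomes from the configured families with
#' person-time / session offsets and shared cluster random intercepts.
#' MAR missingness is then imposed on the maskable covariates.
#'
#' Counts are generated per followed school year through a shared pupil
#' gamma frailty, so yearly components sum to a negative-binomial total
#' with the configured dispersion; cumulative Year-1/Year-2 components are
#' retained (columns suffixed `_y2`) to support restricted-follow-up
#' sensitivity analyses. Same-day overlap between A&E attendance and
#' admission is deduplicated into the unplanned-days total.
#'
#' The returned tibble carries the full potential-outcome bookkeeping
#' (linear predictors under every arm and the true assignment
#' probabilities) as attributes, consumed by [true_marginal_effects()].
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; identical config and seed give a byte-identical
#'   cohort.
#' @param apply_missingness Mask covariates per the config's MAR law
#'   (default `TRUE`).
#' @return A tibble of class `pupil_cohort`, one row per pupil.
#' @examples
#' coh <- generate_cohort(cohort_config(n_pupils = 300, n_clusters = 15), seed = 1)
#' table(coh$treatment)
#' @export
generate_cohort <- function(config, seed, apply_missingness = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_pupils

  # unequal cluster sizes via Dirichlet-ish weights; every cluster non-empty
  w <- rgamma(config$n_clusters, shape = 4, rate = 1)
  cluster_id <- sample.int(config$n_clusters, n, replace = TRUE, prob = w / sum(w))

  covs <- draw_covariates(n, cluster_id, config)
  X <- generator_design(covs, config$covariates)

  trt <- assign_treatment(X, config$ps_coefficients)
  treatment <- trt$treatment

  # cluster random intercepts, one per outcome
  bmat <- vapply(config$outcome_specs, function(s) {
    rnorm(config$n_clusters, 0, s$cluster_sd)
  }, numeric(config$n_clusters))
  if (config$n_clusters == 1) bmat <- matrix(bmat, nrow = 1,
                                             dimnames = list(NULL, names(config$outcome_specs)))

  fup <- draw_followup(covs$academic_year, config)

  out <- simulate_outcomes(X, treatment, config, bmat[cluster_id, , drop = FALSE], fup)

  cohort <- dplyr::bind_cols(
    tibble::tibble(
      pupil_id = seq_len(n),
      cluster_id = cluster_id,
      treatment = treatment,
      true_ps_support = trt$probs[, "Support"] /
        (trt$probs[, "Support"] + trt$probs[, "None"]),
      true_ps_ehcp = trt$probs[, "EHCP"] /
        (trt$probs[, "EHCP"] + trt$probs[, "None"])
    ),
    covs, fup, out$realised
  )

  if (apply_missingness && length(config$missingness) > 0) {
    cohort <- impose_missingness(cohort, config$missingness, design = X)
  } else {
    for (nm in names(config$missingness)) {
      cohort[[paste0("miss_", nm)]] <- 0L
    }
  }

  attr(cohort, "config") <- config
  attr(cohort, "po") <- out$po
  class(cohort) <- c("pupil_cohort", class(cohort))
  cohort
}

# ---- confounders -----------------------------------------------------------

draw_cat <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

draw_covariates <- function(n, cluster_id, config) {
  cv <- config$covariates
  idaci <- draw_cat(n, cv$categorical$idaci)
  # deprivation gradient in free-school-meal eligibility (marginal ~0.197)
  p_fsm <- c(q1_most = 0.33, q2 = 0.23, q3 = 0.16, q4 = 0.11, q5_least = 0.075)
  fsm <- factor(ifelse(runif(n) < p_fsm[as.character(idaci)],
                       "Eligible", "NotEligible"),
                levels = names(cv$categorical$fsm))

  gender <- draw_cat(n, cv$categorical$gender)
  gest_age <- draw_cat(n, cv$categorical$gest_age)
  # birthweight depends on gestational age
  bw_lv <- names(cv$categorical$birthweight)
  bw_probs <- rbind(
    "39+w" = c(0.545, 0.415, 0.04), "37-38w" = c(0.60, 0.32, 0.08),
    "35-36w" = c(0.55, 0.20, 0.25), "<=34w" = c(0.38, 0.12, 0.50)
  )
  birthweight <- factor(vapply(as.character(gest_age), function(g) {
    sample(bw_lv, 1, prob = bw_probs[g, ])
  }, character(1)), levels = bw_lv)

  maternal_age <- draw_cat(n, cv$categorical$maternal_age)
  ethnicity <- draw_cat(n, cv$categorical$ethnicity)
  language <- draw_cat(n, cv$categorical$language)
  academic_year <- draw_cat(n, cv$categorical$academic_year)
  cleft_type <- draw_cat(n, cv$categorical$cleft_type)

  severe <- as.integer(cleft_type %in% c("PalateOnly", "Bilateral"))
  cleft_mult <- ifelse(cleft_type == "LipOnly", 0.6, ifelse(severe == 1, 1.5, 1))
  chr <- cv$chronic
  chronic_blood <- as.integer(runif(n) < pmin(1, chr[["chronic_blood"]] * cleft_mult))
  chronic_mental <- as.integer(runif(n) < pmin(1, chr[["chronic_mental"]] * cleft_mult))
  chronic_endo <- as.integer(runif(n) < pmin(1, chr[["chronic_endo"]] * cleft_mult))
  chronic_nonspec <- as.integer(runif(n) < pmin(1, chr[["chronic_nonspec"]] * cleft_mult))
  chronic_other <- as.integer(runif(n) < pmin(1, chr[["chronic_other"]] * cleft_mult))
  chronic_any <- as.integer(chronic_blood | chronic_mental | chronic_endo |
                              chronic_nonspec | chronic_other)

  relative_age <- sample(0:11, n, replace = TRUE)
  fsm_num <- as.integer(fsm == "Eligible")
  eyfsp_z <- -0.28 * fsm_num - 0.45 * chronic_any - 0.35 * severe -
    0.30 * (gest_age == "<=34w") + 0.02 * (relative_age - 5.5) + rnorm(n, 0.3, 0.9)

  ph <- cv$continuous$prior_hosp_rate
  prior_hosp_rate <- rgamma(n, shape = ph$shape,
                            scale = ph$mean / ph$shape) *
    exp(0.45 * chronic_any + 0.25 * severe)

  # school-level composition: cluster mean plus pupil-level (school) noise
  sen_m <- cv$continuous$school_sen_prop
  fsm_m <- cv$continuous$school_fsm_prop
  cl_sen <- rbeta(max(cluster_id), sen_m$mean * sen_m$conc,
                  (1 - sen_m$mean) * sen_m$conc)
  cl_fsm <- rbeta(max(cluster_id), fsm_m$mean * fsm_m$conc,
                  (1 - fsm_m$mean) * fsm_m$conc)
  school_sen_prop <- pmin(0.6, pmax(0.005,
    cl_sen[cluster_id] + rnorm(n, 0, 0.03)))
  school_fsm_prop <- pmin(0.9, pmax(0.005,
    cl_fsm[cluster_id] + rnorm(n, 0, 0.05) + 0.10 * fsm_num))

  nursery <- as.integer(runif(n) < cv$nursery)

  tibble::tibble(
    gender, gest_age, birthweight, maternal_age, ethnicity, language,
    idaci, fsm, academic_year, cleft_type,
    chronic_blood, chronic_mental, chronic_endo, chronic_nonspec,
    chronic_any, nursery,
    eyfsp_z, relative_age, prior_hosp_rate, school_sen_prop, school_fsm_prop
  )
}

# model matrix on the generator design, column names fixed by
# generator_design_names()
generator_design <- function(covs, covariates = default_covariate_marginals()) {
  cat_cols <- lapply(names(covariates$categorical), function(v) {
    if (v == "academic_year") return(NULL)
    lv <- names(covariates$categorical[[v]])
    m <- vapply(lv[-1], function(l) as.numeric(covs[[v]] == l),
                numeric(nrow(covs)))
    colnames(m) <- paste0(v, lv[-1])
    m
  })
  cat_mat <- do.call(cbind, cat_cols)
  year_trend <- as.numeric(covs$academic_year) - 6
  X <- cbind(
    "(Intercept)" = 1, cat_mat, year_trend = year_trend,
    chronic_blood = covs$chronic_blood, chronic_mental = covs$chronic_mental,
    chronic_endo = covs$chronic_endo, chronic_nonspec = covs$chronic_nonspec,
    chronic_any = covs$chronic_any, nursery = covs$nursery,
    eyfsp_z = covs$eyfsp_z, relative_age = covs$relative_age,
    prior_hosp_rate = covs$prior_hosp_rate,
    school_sen_prop = covs$school_sen_prop,
    school_fsm_prop = covs$school_fsm_prop
  )
  stopifnot(identical(colnames(X), generator_design_names(covariates)))
  X
}

# ---- treatment -------------------------------------------------------------

#' Draw treatment from the multinomial-logit assignment law
#'
#' Computes the three-arm assignment probabilities
#' `softmax(0, X b_Support, X b_EHCP)` and draws one level per pupil.
#'
#' @param design Numeric design matrix (rows = pupils) whose columns match
#'   the coefficient names.
#' @param ps_coefficients Named list with vectors `Support` and `EHCP` of
#'   log-odds versus `None`.
#' @return List with `treatment` (factor None/Support/EHCP) and `probs`
#'   (matrix of assignment probabilities, rows summing to one).
#' @examples
#' X <- cbind("(Intercept)" = rep(1, 5))
#' assign_treatment(X, list(Support = c("(Intercept)" = log(0.5)),
#'                          EHCP = c("(Intercept)" = log(0.1))))$probs[1, ]
#' @export
assign_treatment <- function(design, ps_coefficients) {
  bS <- ps_coefficients$Support
  bE <- ps_coefficients$EHCP
  stopifnot(all(names(bS) %in% colnames(design)),
            all(names(bE) %in% colnames(design)))
  etaS <- drop(design[, names(bS), drop = FALSE] %*% bS)
  etaE <- drop(design[, names(bE), drop = FALSE] %*% bE)
  if (any(!is.finite(etaS)) || any(!is.finite(etaE))) {
    stop("non-finite treatment linear predictor", call. = FALSE)
  }
  denom <- 1 + exp(etaS) + exp(etaE)
  probs <- cbind(None = 1 / denom, Support = exp(etaS) / denom,
                 EHCP = exp(etaE) / denom)
  u <- runif(nrow(design))
  lev <- ifelse(u < probs[, "None"], "None",
                ifelse(u < probs[, "None"] + probs[, "Support"],
                       "Support", "EHCP"))
  list(treatment = factor(lev, levels = c("None", "Support", "EHCP")),
       probs = probs)
}

# ---- follow-up calendar ----------------------------------------------------

# Entry cohorts are followed from Year 1 up to Year 6 or the administrative
# end of the study, whichever is earlier: cohort k of 11 is followed for
# min(6, 12 - k) school years. KS1 requires >= 2 years, KS2 >= 6.
draw_followup <- function(academic_year, config) {
  k <- as.integer(academic_year)
  years <- pmin(6L, 12L - k)
  n <- length(k)
  sess_py <- matrix(rpois(n * 6, config$sessions_per_year), n, 6)
  sess_py[outer(seq_len(n), 1:6, function(i, y) y > years[i])] <- 0L
  # a small fraction of pupils lack absence data entirely
  no_sess <- runif(n) < 0.0008
  sess_py[no_sess, ] <- 0L
  tibble::tibble(
    years_followed = years,
    followup_years = years,
    followup_days = as.integer(round(365.25 * years)),
    sessions_possible = as.integer(rowSums(sess_py)),
    sessions_possible_y2 = as.integer(rowSums(sess_py[, 1:2, drop = FALSE])),
    .sess_py = I(asplit(sess_py, 1))
  )
}

# ---- outcomes --------------------------------------------------------------

#' Simulate outcomes for given covariates and treatment
#'
#' Count outcomes are drawn per followed school year as Poisson draws with
#' mean `offset_y * exp(linear predictor) * G * exp(b)`, where `G` is a
#' pupil gamma frailty with the configured dispersion and `b` a cluster
#' random intercept; totals are therefore negative binomial. Scores are
#' normal. A&E and admitted days overlapping on the same day are
#' deduplicated into `hosp_days_unplanned`.
#'
#' @param design Generator design matrix.
#' @param treatment Factor of assigned levels.
#' @param config A [cohort_config()].
#' @param cluster_effects Matrix (pupils x outcomes) of cluster random
#'   intercepts on the link scale.
#' @param followup Follow-up tibble from the generator (yearly session and
#'   day denominators).
#' @return List with `realised` (tibble of outcome columns) and `po`
#'   (potential-outcome bookkeeping: link-scale linear predictors per arm).
#' @keywords internal
#' @export
simulate_outcomes <- function(design, treatment, config, cluster_effects,
                              followup) {
  n <- nrow(design)
  specs <- config$outcome_specs
  arms <- config$treatment_levels
  years <- followup$years_followed

  lp_arm <- function(spec) {
    base_lp <- spec$base + drop(design %*% spec$coef)
    sapply(arms, function(a) {
      eff <- if (a == "None") 0 else spec$effects[[a]]
      base_lp + eff
    })
  }
  po <- lapply(specs, lp_arm)  # list of n x 3 matrices, link scale, no cluster/frailty

  eff_realised <- function(spec) {
    ifelse(treatment == "None", 0, spec$effects[as.character(treatment)])
  }

  sim_count_yearly <- function(nm, offset_py) {
    spec <- specs[[nm]]
    eta <- spec$base + drop(design %*% spec$coef) + eff_realised(spec) +
      cluster_effects[, nm]
    G <- rgamma(n, shape = spec$dispersion, rate = spec$dispersion)
    mu <- exp(eta) * G
    ymat <- matrix(0L, n, 6)
    for (y in 1:6) {
      act <- years >= y
      ymat[act, y] <- rpois(sum(act), offset_py[act, y] * mu[act])
    }
    ymat
  }

  if (any(!vapply(followup$.sess_py, is.numeric, logical(1)))) {
    stop("per-year session components missing", call. = FALSE)
  }
  sess_py <- do.call(rbind, followup$.sess_py)
  day_py <- matrix(1, n, 6)  # one follow-up year per school year

  ae_py <- sim_count_yearly("hosp_ae", day_py)
  apc_py <- sim_count_yearly("hosp_apc", day_py)
  # same-day overlap: some admitted days started at A&E on the same day
  ov_py <- matrix(rbinom(n * 6, pmin(ae_py, apc_py), config$overlap_prob), n, 6)
  unp_py <- pmin(ae_py + apc_py - ov_py, 365L)

  med_py <- sim_count_yearly("sessions_medical", sess_py)
  una_py <- sim_count_yearly("sessions_unauth", sess_py)
  oth_py <- sim_count_yearly("sessions_other", sess_py)
  # absences cannot exceed possible sessions: proportional thinning (rare)
  tot_py <- med_py + una_py + oth_py
  over <- tot_py > sess_py
  if (any(over)) {
    sc <- ifelse(over, sess_py / pmax(tot_py, 1L), 1)
    med_py <- floor(med_py * sc); una_py <- floor(una_py * sc)
    oth_py <- floor(oth_py * sc)
  }

  sim_score <- function(nm, min_years) {
    spec <- specs[[nm]]
    eta <- spec$base + drop(design %*% spec$coef) + eff_realised(spec) +
      cluster_effects[, nm]
    y <- eta + rnorm(n, 0, spec$sd)
    sat <- runif(n) < config$score_sit_prob
    y[years < min_years | !sat] <- NA_real_
    y
  }
  ks1 <- sim_score("ks1", 2L)
  ks2 <- sim_score("ks2", 6L)

  realised <- tibble::tibble(
    hospital_days_ae = as.integer(rowSums(ae_py)),
    hospital_days_apc = as.integer(rowSums(apc_py)),
    hospital_days_unplanned = as.integer(rowSums(unp_py)),
    hospital_days_ae_y2 = as.integer(rowSums(ae_py[, 1:2, drop = FALSE])),
    hospital_days_apc_y2 = as.integer(rowSums(apc_py[, 1:2, drop = FALSE])),
    hospital_days_unplanned_y2 = as.integer(rowSums(unp_py[, 1:2, drop = FALSE])),
    sessions_medical = as.integer(rowSums(med_py)),
    sessions_unauth = as.integer(rowSums(una_py)),
    sessions_other = as.integer(rowSums(oth_py)),
    sessions_medical_y2 = as.integer(rowSums(med_py[, 1:2, drop = FALSE])),
    sessions_unauth_y2 = as.integer(rowSums(una_py[, 1:2, drop = FALSE])),
    sessions_other_y2 = as.integer(rowSums(oth_py[, 1:2, drop = FALSE])),
    ks1_raw = ks1, ks2_raw = ks2
  )

  if (config$persistent_mode == "logistic") {
    spec <- specs$persistent
    eta <- spec$base + drop(design %*% spec$coef) + eff_realised(spec) +
      cluster_effects[, "persistent"]
    realised$persistent_direct <- as.integer(runif(n) < plogis(eta))
  }

  list(realised = realised, po = po)
}

# ---- missingness -----------------------------------------------------------

#' Impose missing-at-random masking on covariates
#'
#' Masks each configured covariate with probability following a logistic
#' law on fully observed covariates (MAR): categorical values become `NA`
#' (rendered as an explicit `"Unknown"` level by
#' [derive_analysis_table()]), continuous values become `NA`; a
#' `miss_<covariate>` indicator column records each mask.
#'
#' @param cohort A `pupil_cohort` tibble (or any tibble with the named
#'   covariates).
#' @param missingness Named list of masking laws (`rate` plus logistic
#'   `slopes` on the generator design); see [default_missingness()].
#' @param design Optional pre-computed generator design matrix.
#' @return The cohort with masked values and `miss_*` flags.
#' @export
impose_missingness <- function(cohort, missingness, design = NULL) {
  if (is.null(design)) {
    cfg <- attr(cohort, "config")
    cvs <- if (!is.null(cfg)) cfg$covariates else default_covariate_marginals()
    design <- generator_design(cohort, cvs)
  }
  for (nm in names(missingness)) {
    if (!nm %in% colnames(cohort)) {
      stop("missingness spec refers to unknown covariate: ", nm, call. = FALSE)
    }
    sp <- missingness[[nm]]
    slopes <- sp$slopes
    eta_x <- if (length(slopes) > 0) {
      drop(design[, names(slopes), drop = FALSE] %*% slopes)
    } else rep(0, nrow(cohort))
    flag <- paste0("miss_", nm)
    if (sp$rate <= 0) {
      cohort[[flag]] <- 0L
      next
    }
    # intercept solved so the marginal masking rate matches `rate`
    f <- function(a) mean(plogis(a + eta_x)) - sp$rate
    a0 <- stats::uniroot(f, c(-20, 20))$root
    mask <- runif(nrow(cohort)) < plogis(a0 + eta_x)
    cohort[[flag]] <- as.integer(mask)
    cohort[[nm]][mask] <- NA
  }
  cohort
}

# ---- I/O -------------------------------------------------------------------

#' Write / read a cohort with its JSON sidecar
#'
#' The cohort is written as a plain CSV (one row per pupil); generator
#' config, seed and any oracle truth travel in a `<path>.json` sidecar so
#' a round trip restores factor levels and metadata.
#'
#' @param cohort A `pupil_cohort` tibble.
#' @param path CSV file path.
#' @param truth Optional [true_marginal_effects()] result to embed.
#' @return `write_cohort()`: `path`, invisibly. `read_cohort()`: the cohort
#'   tibble (attribute `truth` if present in the sidecar).
#' @export
write_cohort <- function(cohort, path, truth = NULL) {
  out <- dplyr::select(as.data.frame(cohort), -dplyr::any_of(".sess_py"))
  readr::write_csv(out, path, na = "")
  cfg <- attr(cohort, "config")
  side <- list(
    columns = lapply(out, function(x) if (is.factor(x)) levels(x) else class(x)[1]),
    persistent_mode = if (!is.null(cfg)) cfg$persistent_mode else NULL,
    truth = truth
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    for (nm in names(side$columns)) {
      lv <- side$columns[[nm]]
      if (length(lv) > 1 && nm %in% names(x)) x[[nm]] <- factor(x[[nm]], levels = lv)
    }
    if (!is.null(side$truth)) attr(x, "truth") <- side$truth
  }
  class(x) <- c("pupil_cohort", class(x))
  x
}
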