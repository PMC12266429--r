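#' Yearly / per-session rates per 1000 units of exposure
#'
#' @param numerator Event count(s).
#' @param denominator Exposure (follow-up years, or possible sessions);
#'   must be strictly positive.
#' @return `numerator / denominator * 1000`.
#' @examples
#' rate_per_1000(10, 2)    # 5000 per 1000 years
#' @export
rate_per_1000 <- function(numerator, denominator) {
  if (any(!is.na(denominator) & denominator <= 0)) {
    stop("exposure denominator must be > 0", call. = FALSE)
  }
  numerator / denominator * 1000
}

#' Persistent-absence flag (>= 10 percent of possible sessions missed)
#'
#' Boundary inclusive: exactly 10 percent counts as persistent. Pupils with
#' no recorded possible sessions get `NA` (excluded from absence analyses).
#'
#' @param missed_sessions Total absence sessions (all types) over follow-up.
#' @param possible_sessions Total possible half-day sessions.
#' @param threshold Absence fraction defining persistence (default 0.10).
#' @return Logical vector (NA where `possible_sessions` is 0).
#' @examples
#' flag_persistent(c(40, 39), c(400, 400))  # TRUE FALSE
#' @export
flag_persistent <- function(missed_sessions, possible_sessions,
                            threshold = 0.10) {
  if (any(!is.na(possible_sessions) & possible_sessions < 0)) {
    stop("possible_sessions must be >= 0", call. = FALSE)
  }
  out <- missed_sessions / possible_sessions >= threshold
  out[!is.na(possible_sessions) & possible_sessions == 0] <- NA
  out
}

#' Deduplicated unplanned hospital days
#'
#' A day with both an A&E attendance and an admission counts once: the
#' unplanned-days total is the size of the union of the two day sets.
#'
#' @param apc_day_set,ae_day_set Vectors of day indices (one pupil), or
#'   lists of such vectors (one element per pupil).
#' @return Integer count(s) of distinct hospital days.
#' @examples
#' dedupe_hospital_days(c(1, 2), c(2, 3))  # 3
#' @export
dedupe_hospital_days <- function(apc_day_set, ae_day_set) {
  if (is.list(apc_day_set) || is.list(ae_day_set)) {
    return(purrr::map2_int(apc_day_set, ae_day_set,
                           function(a, e) length(union(a, e))))
  }
  length(union(apc_day_set, ae_day_set))
}

#' Standardise scores within academic year
#'
#' Centres and scales raw scores to mean 0, sd 1 within each academic-year
#' group, using the population (divide-by-n) standard deviation. Missing
#' scores are propagated; a year group whose non-missing scores have zero
#' variance is a domain error.
#'
#' @param raw_scores Numeric scores.
#' @param academic_year Grouping factor.
#' @return Numeric z-scores, same length and order.
#' @examples
#' standardise_scores(c(1, 2, 3), rep("y1", 3))
#' @export
standardise_scores <- function(raw_scores, academic_year) {
  stopifnot(length(raw_scores) == length(academic_year))
  out <- rep(NA_real_, length(raw_scores))
  for (g in unique(academic_year[!is.na(raw_scores)])) {
    i <- which(academic_year == g & !is.na(raw_scores))
    if (length(i) < 2) {
      stop("need >= 2 non-missing scores in year group ", g, call. = FALSE)
    }
    x <- raw_scores[i]
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) stop("zero score variance in year group ", g, call. = FALSE)
    out[i] <- (x - mean(x)) / s
  }
  out
}

#' Progress score relative to school readiness
#'
#' Difference between a key-stage z-score and the school-entry (EYFSP)
#' z-score; absent if either is missing.
#'
#' @param ks_z,eyfsp_z Year-standardised z-scores.
#' @return `ks_z - eyfsp_z`.
#' @export
progress_score <- function(ks_z, eyfsp_z) ks_z - eyfsp_z

# covariate roles shared by the propensity and outcome models
confounder_vars <- function() {
  c("gender", "gest_age", "birthweight", "maternal_age", "ethnicity",
    "language", "idaci", "fsm", "academic_year", "cleft_type",
    "chronic_blood", "chronic_mental", "chronic_endo", "chronic_nonspec",
    "chronic_any", "nursery",
    "eyfsp_z", "relative_age", "prior_hosp_rate",
    "school_sen_prop", "school_fsm_prop")
}

#' Continuous confounders (modelled with linear + quadratic terms)
#' @return Character vector of column names.
#' @export
continuous_confounders <- function() {
  c("eyfsp_z", "relative_age", "prior_hosp_rate",
    "school_sen_prop", "school_fsm_prop")
}

#' Derive the analysis table from a raw cohort
#'
#' Adds all derived analysis variables: yearly unplanned-hospitalisation
#' rate and per-session absence rates (per 1000), the persistent-absence
#' flag, year-standardised KS1/KS2/EYFSP z-scores and progress scores, and
#' the missing-covariate treatment (categorical missing values become an
#' explicit `"Unknown"` level; continuous values stay `NA` until
#' [apply_mcim()] zero-fills them for modelling).
#'
#' @param cohort A `pupil_cohort` tibble (generated or read from CSV).
#' @param persistent `"derived"`: flag from simulated/recorded session
#'   counts (default); `"direct"`: use a directly generated binary column
#'   `persistent_direct` if present.
#' @return The analysis tibble (class `analysis_table`).
#' @export
derive_analysis_table <- function(cohort, persistent = c("derived", "direct")) {
  persistent <- match.arg(persistent)
  tbl <- tibble::as_tibble(cohort)
  tbl$.sess_py <- NULL

  for (v in intersect(c("gest_age", "birthweight", "maternal_age", "idaci",
                        "language", "ethnicity"), names(tbl))) {
    if (any(is.na(tbl[[v]]))) {
      lv <- levels(tbl[[v]]) %||% sort(unique(stats::na.omit(tbl[[v]])))
      tbl[[v]] <- factor(ifelse(is.na(as.character(tbl[[v]])), "Unknown",
                                as.character(tbl[[v]])),
                         levels = c(lv, "Unknown"))
    }
  }

  tbl$rate_hosp <- rate_per_1000(tbl$hospital_days_unplanned, tbl$followup_years)
  sess_ok <- tbl$sessions_possible > 0
  tbl$rate_medical <- ifelse(sess_ok,
    tbl$sessions_medical / tbl$sessions_possible * 1000, NA_real_)
  tbl$rate_unauth <- ifelse(sess_ok,
    tbl$sessions_unauth / tbl$sessions_possible * 1000, NA_real_)

  missed_total <- tbl$sessions_medical + tbl$sessions_unauth +
    (tbl$sessions_other %||% 0)
  if (persistent == "direct" && "persistent_direct" %in% names(tbl)) {
    tbl$persistent_flag <- as.logical(tbl$persistent_direct)
  } else {
    tbl$persistent_flag <- flag_persistent(missed_total, tbl$sessions_possible)
  }

  yr <- tbl$academic_year
  std_or_na <- function(x) {
    if (is.null(x) || all(is.na(x))) return(NA_real_)
    standardise_scores(x, yr)
  }
  tbl$ks1_z <- std_or_na(tbl$ks1_raw)
  tbl$ks2_z <- std_or_na(tbl$ks2_raw)
  eyfsp_src <- tbl$eyfsp_z
  tbl$eyfsp_zy <- standardise_scores(eyfsp_src, yr)
  tbl$progress_ks1 <- progress_score(tbl$ks1_z, tbl$eyfsp_zy)
  tbl$progress_ks2 <- progress_score(tbl$ks2_z, tbl$eyfsp_zy)

  class(tbl) <- c("analysis_table", class(tbl))
  attr(tbl, "config") <- attr(cohort, "config")
  tbl
}

#' Missing-covariate indicator (MCIM) design expansion
#'
#' Zero-fills missing continuous covariates (their `miss_*` indicator
#' columns record the masking) and checks that categorical missing values
#' are represented as an explicit `"Unknown"` level. Both the zero-filled
#' value and the indicator enter downstream models; the expansion
#' round-trips to the original design when nothing is missing.
#'
#' @param table An analysis tibble.
#' @param maskable Continuous covariates to zero-fill (default: the
#'   continuous confounders with a `miss_*` companion column).
#' @return The table with zero-filled continuous covariates; attribute
#'   `mcim_terms` lists the model terms (confounders plus indicators).
#' @export
apply_mcim <- function(table, maskable = NULL) {
  if (is.null(maskable)) {
    maskable <- intersect(continuous_confounders(),
                          sub("^miss_", "", grep("^miss_", names(table), value = TRUE)))
  }
  for (v in maskable) {
    fl <- paste0("miss_", v)
    if (!fl %in% names(table)) {
      table[[fl]] <- as.integer(is.na(table[[v]]))
    }
    table[[v]][is.na(table[[v]]) | table[[fl]] == 1L] <- 0
  }
  # categorical maskables carry their own "Unknown" level, so only the
  # continuous indicators enter as separate terms (else exact collinearity)
  terms <- c(intersect(confounder_vars(), names(table)),
             paste0("miss_", intersect(maskable, names(table))))
  terms <- intersect(unique(terms), c(names(table)))
  attr(table, "mcim_terms") <- terms
  table
}

#' Restrict follow-up to the end of Year 2
#'
#' Re-accumulates numerators and denominators to the restricted horizon
#' using the retained Year-1/Year-2 components, recomputes rates and the
#' persistent-absence flag, and drops KS2 outcomes (not yet observable at
#' the horizon).
#'
#' @param table An analysis tibble carrying `*_y2` component columns.
#' @param horizon 2 (censor at end of Year 2) or 6 (identity).
#' @return The restricted analysis tibble.
#' @export
restrict_followup <- function(table, horizon = 2) {
  if (!horizon %in% c(2, 6)) stop("horizon must be 2 or 6", call. = FALSE)
  if (horizon == 6) return(table)
  need <- c("hospital_days_unplanned_y2", "sessions_possible_y2",
            "sessions_medical_y2", "sessions_unauth_y2")
  if (!all(need %in% names(table))) {
    stop("Year-2 component columns are not available", call. = FALSE)
  }
  table$followup_years <- pmin(table$followup_years, 2)
  table$followup_days <- pmin(table$followup_days, as.integer(round(2 * 365.25)))
  table$hospital_days_unplanned <- table$hospital_days_unplanned_y2
  table$hospital_days_ae <- table$hospital_days_ae_y2 %||% table$hospital_days_ae
  table$hospital_days_apc <- table$hospital_days_apc_y2 %||% table$hospital_days_apc
  table$sessions_possible <- table$sessions_possible_y2
  table$sessions_medical <- table$sessions_medical_y2
  table$sessions_unauth <- table$sessions_unauth_y2
  if ("sessions_other_y2" %in% names(table)) {
    table$sessions_other <- table$sessions_other_y2
  }
  table$rate_hosp <- rate_per_1000(table$hospital_days_unplanned,
                                   table$followup_years)
  sess_ok <- table$sessions_possible > 0
  table$rate_medical <- ifelse(sess_ok,
    table$sessions_medical / table$sessions_possible * 1000, NA_real_)
  table$rate_unauth <- ifelse(sess_ok,
    table$sessions_unauth / table$sessions_possible * 1000, NA_real_)
  missed_total <- table$sessions_medical + table$sessions_unauth +
    (table$sessions_other %||% 0)
  table$persistent_flag <- flag_persistent(missed_total, table$sessions_possible)
  table$ks2_z <- NA_real_
  table$progress_ks2 <- NA_real_
  table
}

#' Complete-records filter
#'
#' Restricts to pupils with no masked covariate (all `miss_*` indicators
#' zero), for the complete-records sensitivity analysis.
#'
#' @param table An analysis tibble with `miss_*` columns.
#' @return The filtered tibble; attribute `retained_fraction`.
#' @export
complete_records_filter <- function(table) {
  flags <- grep("^miss_", names(table), value = TRUE)
  if (length(flags) == 0) return(table)
  keep <- rowSums(as.matrix(table[flags])) == 0
  if (!any(keep)) stop("no complete records remain", call. = FALSE)
  out <- table[keep, , drop = FALSE]
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Eligibility filter (flag pass-through)
#'
#' Drops pupils flagged ineligible for the emulated trial: a major
#' congenital anomaly, an unknown cleft subtype, or non-mainstream
#' schooling in Year 1. Columns that are absent are treated as "all
#' eligible", so the function is the identity on generated cohorts (which
#' emit eligible pupils only).
#'
#' @param table A cohort or analysis tibble.
#' @return The filtered tibble.
#' @export
eligibility_filter <- function(table) {
  keep <- rep(TRUE, nrow(table))
  if ("major_anomaly" %in% names(table)) keep <- keep & table$major_anomaly == 0
  if ("mainstream_school" %in% names(table)) keep <- keep & table$mainstream_school == 1
  if ("cleft_type" %in% names(table)) keep <- keep & !is.na(table$cleft_type)
  table[keep, , drop = FALSE]
}
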