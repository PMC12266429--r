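# consolidated estimate chain for one contrast: shares the PS fit, one
# full-covariate outcome fit (conditional + g-computation) and one
# AIPW outcome fit per outcome, so it is cheap enough to re-run inside
# every bootstrap replicate
contrast_estimates <- function(table, contrast, outcomes, estimators,
                               estimands, covariates, aipw_covariates = NULL,
                               count_family = "negbin") {
  ps_fit <- fit_ps_model(table, contrast, covariates = covariates)
  dat_all <- ps_fit$data
  res <- list()
  for (oc in outcomes) {
    info <- outcome_info(oc)
    dat <- outcome_frame(dat_all, info)
    a <- dat$.a; y <- dat$.y; ex <- dat$.exposure
    fam <- if (info$family == "negbin") count_family else info$family

    if ("crude" %in% estimands) {
      point <- if (info$measure == "RaR") {
        (sum(y[a == 1]) / sum(ex[a == 1])) / (sum(y[a == 0]) / sum(ex[a == 0]))
      } else if (info$family == "logistic") {
        (mean(y[a == 1]) / (1 - mean(y[a == 1]))) /
          (mean(y[a == 0]) / (1 - mean(y[a == 0])))
      } else mean(y[a == 1]) - mean(y[a == 0])
      res[[length(res) + 1]] <- effect_row(
        oc, contrast, "crude", "regression",
        treatment_coef_measure(info, crude = TRUE), point, nrow(dat))
    }

    need_full <- any(c("conditional") %in% estimands) ||
      ("gcomp" %in% estimators && any(c("ATE", "ATT") %in% estimands))
    fit_full <- NULL
    if (need_full) {
      fit_full <- fit_outcome_model(dat, ".y", fam,
                                    covariates = c(".a", covariates),
                                    offset = if (!is.na(info$exposure)) ".exposure")
    }
    if ("conditional" %in% estimands && !is.null(fit_full)) {
      res[[length(res) + 1]] <- effect_row(
        oc, contrast, "conditional", "regression",
        treatment_coef_measure(info), coef_estimate(fit_full, info), nrow(dat))
    }

    causal <- intersect(estimands, c("ATE", "ATT"))
    if (length(causal) > 0) {
      predict_rates <- function(fit) {
        nd1 <- dat; nd1$.a <- 1L
        nd0 <- dat; nd0$.a <- 0L
        m1 <- predict(fit, newdata = nd1, type = "response")
        m0 <- predict(fit, newdata = nd0, type = "response")
        if (info$measure == "RaR") {
          list(m1 = m1 / dat$.exposure, m0 = m0 / dat$.exposure)
        } else list(m1 = m1, m0 = m0)
      }
      if ("IPW" %in% estimators) {
        for (est in causal) {
          res[[length(res) + 1]] <- estimate_ipw(NULL, structure(
            list(contrast = contrast, data = dat), class = "ps_fit"),
            oc, contrast, estimand = est)
        }
      }
      if ("gcomp" %in% estimators && !is.null(fit_full)) {
        pr <- predict_rates(fit_full)
        for (est in causal) {
          s <- if (est == "ATE") rep(TRUE, nrow(dat)) else a == 1
          r1 <- pr$m1[s]; r0 <- pr$m0[s]
          point <- if (info$measure == "RaR") {
            sum(r1 * dat$.exposure[s]) / sum(r0 * dat$.exposure[s])
          } else if (info$measure == "delta") mean(r1) - mean(r0)
          else mean(r1) / mean(r0)
          res[[length(res) + 1]] <- effect_row(oc, contrast, est, "gcomp",
                                               info$measure, point, nrow(dat))
        }
      }
      if ("AIPW" %in% estimators) {
        acov <- (aipw_covariates[[oc]] %||% covariates)
        aipw_fam <- switch(info$family, negbin = "poisson", info$family)
        fit_aipw <- if (!is.null(fit_full) && identical(acov, covariates) &&
                          identical(aipw_fam, attr(fit_full, "family_used"))) {
          fit_full  # same model: reuse instead of refitting
        } else {
          fit_outcome_model(dat, ".y", aipw_fam, covariates = c(".a", acov),
                            offset = if (!is.na(info$exposure)) ".exposure")
        }
        mr <- predict_rates(fit_aipw)
        yr <- if (info$measure == "RaR") dat$.y / dat$.exposure else dat$.y
        p <- dat$ps
        for (est in causal) {
          if (est == "ATE") {
            psi1 <- mean(a / p * (yr - mr$m1) + mr$m1)
            psi0 <- mean((1 - a) / (1 - p) * (yr - mr$m0) + mr$m0)
          } else {
            n1 <- sum(a)
            psi1 <- sum(a * yr) / n1
            wr <- (1 - a) * p / (1 - p)
            psi0 <- sum(a * mr$m0) / n1 + sum(wr * (yr - mr$m0)) / sum(wr)
          }
          point <- if (info$measure == "delta") psi1 - psi0 else psi1 / psi0
          res[[length(res) + 1]] <- effect_row(
            oc, contrast, est, "AIPW", info$measure, point, nrow(dat),
            list(family = attr(fit_aipw, "family_used"),
                 att_extension = est == "ATT"))
        }
      }
    }
  }
  out <- dplyr::bind_rows(res)
  attr(out, "ps_fit") <- ps_fit
  out
}

estimates_vector <- function(est) {
  setNames(est$estimate,
           paste(est$outcome, est$estimand, est$estimator, sep = "."))
}

#' Run the full emulated-trial analysis
#'
#' For each contrast: fits the propensity model, applies the positivity
#' gate (a failing contrast is refused with an explicit report, never a
#' crash), computes crude and conditional associations and the requested
#' causal estimators for ATE and ATT, and attaches cluster-bootstrap
#' percentile confidence intervals in which the whole chain (propensity
#' fit included) is re-run per replicate.
#'
#' @param cohort A `pupil_cohort` or pre-derived analysis tibble.
#' @param contrasts List of `c(exposed, reference)` pairs.
#' @param outcomes Outcome names (see [analysis_outcomes()]).
#' @param estimators Causal estimators among `"IPW"`, `"gcomp"`, `"AIPW"`.
#' @param estimands Among `"crude"`, `"conditional"`, `"ATE"`, `"ATT"`.
#' @param B Bootstrap replicates (0 skips interval estimation).
#' @param seed Integer seed controlling the bootstrap resampling.
#' @param use_lasso Select AIPW outcome-model covariates by
#'   cross-validated lasso once on the full data (selection kept fixed
#'   across bootstrap replicates).
#' @param year2_censor Restrict follow-up to the end of Year 2.
#' @param complete_records Drop pupils with any masked covariate.
#' @param disaggregate_hospital Add A&E-only and admission-only day counts
#'   as outcomes.
#' @param min_per_cell Positivity gate threshold per PS decile.
#' @param count_family Family for count outcome models (conditional and
#'   g-computation); AIPW always uses Poisson unless overridden there.
#' @return Object of class `tte_results`.
#' @export
run_pipeline <- function(cohort,
                         contrasts = list(c("Support", "None")),
                         outcomes = c("hosp", "medical", "unauth",
                                      "persistent", "ks1", "ks2"),
                         estimators = c("IPW", "gcomp", "AIPW"),
                         estimands = c("crude", "conditional", "ATE", "ATT"),
                         B = 1000, seed = 1, use_lasso = TRUE,
                         year2_censor = FALSE, complete_records = FALSE,
                         disaggregate_hospital = FALSE,
                         min_per_cell = 5, count_family = "negbin") {
  log <- c(paste0("seed: ", seed), paste0("B: ", B))
  tbl <- if (inherits(cohort, "analysis_table")) cohort else
    derive_analysis_table(cohort)
  tbl <- eligibility_filter(tbl)
  if (year2_censor) {
    tbl <- restrict_followup(tbl, horizon = 2)
    outcomes <- setdiff(outcomes, c("ks2", "progress_ks2"))
    log <- c(log, "sensitivity: follow-up censored at end of Year 2")
  }
  if (complete_records) {
    tbl <- complete_records_filter(tbl)
    log <- c(log, sprintf("sensitivity: complete records (%.1f%% retained)",
                          100 * attr(tbl, "retained_fraction")))
  }
  if (disaggregate_hospital) {
    tbl <- disaggregate_hospital(tbl)
    outcomes <- union(outcomes, c("hosp_ae", "hosp_apc"))
  }
  tbl <- apply_mcim(tbl)
  covariates <- attr(tbl, "mcim_terms")

  ps_fits <- list(); refusals <- list(); all_est <- list()
  for (ct in contrasts) {
    key <- paste(ct[1], "vs", ct[2])
    ps0 <- fit_ps_model(tbl, ct, covariates = covariates,
                        min_per_cell = min_per_cell)
    ps_fits[[key]] <- ps0
    if (ps0$flag == "fail") {
      refusals[[key]] <- paste0(
        "contrast refused: propensity-score overlap fails positivity (",
        "shared support [", paste(round(ps0$overlap$shared_support, 3),
                                  collapse = ", "), "])")
      log <- c(log, paste0(key, ": ", refusals[[key]]))
      next
    }
    log <- c(log, paste0(key, ": positivity ", ps0$flag, "; analysed"))

    aipw_covs <- NULL
    if (use_lasso && "AIPW" %in% estimators) {
      aipw_covs <- lapply(setNames(outcomes, outcomes), function(oc) {
        lasso_covariates(tbl, ct, oc, covariates, seed = seed)
      })
    }
    est <- contrast_estimates(tbl, ct, outcomes, estimators, estimands,
                              covariates, aipw_covs, count_family)
    if (B > 0) {
      stat <- function(d) {
        estimates_vector(contrast_estimates(d, ct, outcomes, estimators,
                                            estimands, covariates,
                                            aipw_covs, count_family))
      }
      bt <- cluster_bootstrap(tbl, stat, B = B, seed = seed)
      key_v <- paste(est$outcome, est$estimand, est$estimator, sep = ".")
      est$ci_low <- bt$summary$ci_low[match(key_v, bt$summary$term)]
      est$ci_high <- bt$summary$ci_high[match(key_v, bt$summary$term)]
      attr(est, "boot") <- bt
    }
    all_est[[key]] <- est
  }

  structure(list(
    estimates = dplyr::bind_rows(all_est),
    ps = ps_fits,
    positivity = tibble::tibble(
      contrast = names(ps_fits),
      flag = vapply(ps_fits, function(x) x$flag, character(1)),
      analysed = !names(ps_fits) %in% names(refusals)
    ),
    refusals = refusals,
    descriptives = describe_cohort(tbl),
    boot = lapply(all_est, attr, "boot"),
    settings = list(outcomes = outcomes, estimators = estimators,
                    estimands = estimands, B = B, seed = seed,
                    count_family = count_family, use_lasso = use_lasso),
    log = log
  ), class = "tte_results")
}

# lasso selection of AIPW outcome-model covariates (post-lasso refit
# happens inside estimate_aipw on the selected set)
lasso_covariates <- function(tbl, contrast, outcome, covariates, seed = 1) {
  info <- outcome_info(outcome)
  dat <- outcome_frame(restrict_contrast(tbl, contrast), info)
  mm <- model.matrix(as.formula(paste("~", build_rhs(covariates,
                                                     character(0)))), dat)[, -1]
  fam <- switch(info$family, negbin = "poisson", logistic = "binomial",
                linear = "gaussian", poisson = "poisson")
  y <- if (info$family == "logistic") as.numeric(dat$.y) else dat$.y
  off <- if (!is.na(info$exposure)) log(dat$.exposure)
  sel_cols <- lasso_select(mm, y, family = fam, seed = seed,
                           offset = off)
  # map selected design columns back to source terms
  keep <- covariates[vapply(covariates, function(v) {
    any(startsWith(sel_cols, v))
  }, logical(1))]
  if (length(keep) == 0) keep <- character(0)
  keep
}

#' @export
print.tte_results <- function(x, ...) {
  cat("<tte_results>\n")
  print(x$positivity)
  if (length(x$refusals)) {
    for (k in names(x$refusals)) cat("  ", k, ": ", x$refusals[[k]], "\n", sep = "")
  }
  if (nrow(x$estimates %||% tibble::tibble())) {
    print(dplyr::select(x$estimates, -dplyr::any_of("diagnostics")), n = 30)
  }
  invisible(x)
}

#' Hospital-day disaggregation into A&E and admitted components
#'
#' Validates that the per-component day counts are present (and satisfy
#' the accounting identity `AE + APC - overlap = unplanned` implied by
#' same-day deduplication) so both components can be run through the
#' estimator chain with the same follow-up offset.
#'
#' @param table Analysis tibble.
#' @return The table, unchanged, after validation.
#' @export
disaggregate_hospital <- function(table) {
  need <- c("hospital_days_ae", "hospital_days_apc", "hospital_days_unplanned")
  if (!all(need %in% names(table))) {
    stop("component day counts absent; cannot disaggregate", call. = FALSE)
  }
  ov <- table$hospital_days_ae + table$hospital_days_apc -
    table$hospital_days_unplanned
  if (any(ov < -1e-8, na.rm = TRUE)) {
    stop("unplanned days exceed AE + APC: inconsistent components",
         call. = FALSE)
  }
  table
}

# descriptive report tables (covariate and outcome margins by arm)
describe_cohort <- function(tbl) {
  arm <- factor(tbl$treatment)
  cats <- intersect(c("gender", "gest_age", "birthweight", "maternal_age",
                      "ethnicity", "language", "idaci", "fsm",
                      "academic_year", "cleft_type"), names(tbl))
  tab1 <- purrr::map_dfr(cats, function(v) {
    tbl |>
      dplyr::count(.data$treatment, value = as.character(.data[[v]])) |>
      dplyr::group_by(.data$value) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::mutate(characteristic = v, .before = 1)
  })
  tab2 <- tbl |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n = dplyr::n(),
      hosp_days = sum(.data$hospital_days_unplanned),
      followup_years = sum(.data$followup_years),
      rate_hosp_1000y = 1000 * .data$hosp_days / .data$followup_years,
      medical_sessions = sum(.data$sessions_medical),
      possible_sessions = sum(.data$sessions_possible),
      rate_medical_1000s = 1000 * .data$medical_sessions / .data$possible_sessions,
      unauth_sessions = sum(.data$sessions_unauth),
      rate_unauth_1000s = 1000 * .data$unauth_sessions / .data$possible_sessions,
      n_persistent = sum(.data$persistent_flag, na.rm = TRUE),
      pct_persistent = 100 * mean(.data$persistent_flag, na.rm = TRUE),
      ks1_median = median(.data$ks1_z, na.rm = TRUE),
      ks2_median = median(.data$ks2_z, na.rm = TRUE),
      .groups = "drop"
    )
  list(covariates = tab1, outcomes = tab2)
}

#' Render report-style tables from a results bundle
#'
#' Writes machine-readable CSVs at full precision plus a markdown effects
#' table rounded to 2 decimal places, one outcome block per section with
#' rows Crude / Conditional / ATE / ATT and estimator columns in the
#' order Regression, IPW, G-computation, AIPW.
#'
#' @param results A `tte_results` bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
render_tables <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  est <- results$estimates
  p <- file.path(dir, "effects.csv")
  readr::write_csv(dplyr::select(est, -dplyr::any_of("diagnostics")), p)
  paths <- c(paths, p)

  fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", x))
  md <- c("# Estimated effects", "")
  for (oc in unique(est$outcome)) {
    eo <- est[est$outcome == oc, ]
    md <- c(md, paste0("## ", oc, " (", eo$measure[1], ")"), "",
            "| Contrast | Estimand | Regression | IPW | G-computation | AIPW |",
            "|---|---|---|---|---|---|")
    for (ctr in unique(eo$contrast)) {
      for (em in intersect(c("crude", "conditional", "ATE", "ATT"),
                           unique(eo$estimand))) {
        cell <- function(es) {
          r <- eo[eo$estimand == em & eo$estimator == es & eo$contrast == ctr, ]
          if (nrow(r) == 0) return("-")
          ci <- if (!is.na(r$ci_low[1])) {
            paste0(" (", fmt(r$ci_low[1]), ", ", fmt(r$ci_high[1]), ")")
          } else ""
          paste0(fmt(r$estimate[1]), ci)
        }
        md <- c(md, paste0("| ", ctr, " | ", em, " | ", cell("regression"),
                           " | ", cell("IPW"), " | ", cell("gcomp"),
                           " | ", cell("AIPW"), " |"))
      }
    }
    md <- c(md, "")
  }
  p <- file.path(dir, "effects.md")
  writeLines(md, p); paths <- c(paths, p)

  p <- file.path(dir, "descriptives_covariates.csv")
  readr::write_csv(results$descriptives$covariates, p); paths <- c(paths, p)
  p <- file.path(dir, "descriptives_outcomes.csv")
  readr::write_csv(results$descriptives$outcomes, p); paths <- c(paths, p)

  for (k in names(results$ps)) {
    p <- file.path(dir, paste0("ps_overlap_", gsub("[^A-Za-z0-9]+", "_", k), ".csv"))
    readr::write_csv(results$ps[[k]]$overlap$table, p); paths <- c(paths, p)
  }
  p <- file.path(dir, "run_log.txt")
  writeLines(unlist(c(results$log, paste0("refused: ", names(results$refusals)))), p)
  paths <- c(paths, p)
  invisible(paths)
}
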