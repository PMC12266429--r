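#' Published aggregate tables from the national cleft cohort
#'
#' Aggregate descriptive statistics published for the national ECHILD
#' cohort of 6,601 children with isolated cleft lip and/or palate that
#' the generator defaults emulate: arm sizes by Year-1 SEN provision, and
#' outcome numerators and denominators by arm. Individual-level records
#' are access-restricted; these published margins are the only quantities
#' of that cohort that can be recomputed exactly, and they serve as
#' reference inputs for crude-association checks
#' (e.g. [crude_from_aggregates()]).
#'
#' @return `echild_arm_counts()`: tibble of pupils per SEN provision arm.
#'   `echild_outcome_aggregates()`: tibble of per-arm outcome totals
#'   (unplanned hospital days and follow-up years; medical and
#'   unauthorised absence sessions and possible sessions; persistent
#'   absence counts).
#' @export
echild_arm_counts <- function() {
  tibble::tibble(
    treatment = c("None", "Support", "EHCP"),
    n = c(4350L, 2009L, 242L)
  )
}

#' @rdname echild_arm_counts
#' @export
echild_outcome_aggregates <- function() {
  tibble::tibble(
    treatment = c("None", "Support", "EHCP"),
    n = c(4350L, 2009L, 242L),
    hosp_days = c(5634, 3608, 642),
    followup_years = c(16931.2, 8276.6, 994.9),
    n_absence = c(4347L, 2007L, 242L),
    medical_sessions = c(195102, 127338, 18938),
    unauth_sessions = c(50470, 33514, 3279),
    possible_sessions = c(6277697, 3028397, 341017),
    n_persistent = c(314L, 295L, 54L)
  )
}

#' Crude two-arm associations from published aggregates
#'
#' Recomputes crude effect measures from aggregate numerators and
#' denominators: the hospitalisation rate ratio as the ratio of aggregate
#' rates (identical to the treatment-only Poisson-with-offset MLE), and
#' the persistent-absence odds ratio from the 2x2 counts (identical to
#' the treatment-only logistic MLE).
#'
#' @param aggregates Tibble as returned by [echild_outcome_aggregates()].
#' @param contrast `c(exposed, reference)` arm names.
#' @return Tibble with one row per measure (`RaR_hosp`, `RaR_medical`,
#'   `RaR_unauth`, `OR_persistent`) and the crude estimate.
#' @export
crude_from_aggregates <- function(aggregates = echild_outcome_aggregates(),
                                  contrast = c("Support", "None")) {
  e <- aggregates[aggregates$treatment == contrast[1], ]
  r <- aggregates[aggregates$treatment == contrast[2], ]
  stopifnot(nrow(e) == 1, nrow(r) == 1)
  odds <- function(k, n) (k / n) / (1 - k / n)
  tibble::tibble(
    measure = c("RaR_hosp", "RaR_medical", "RaR_unauth", "OR_persistent"),
    estimate = c(
      (e$hosp_days / e$followup_years) / (r$hosp_days / r$followup_years),
      (e$medical_sessions / e$possible_sessions) /
        (r$medical_sessions / r$possible_sessions),
      (e$unauth_sessions / e$possible_sessions) /
        (r$unauth_sessions / r$possible_sessions),
      odds(e$n_persistent, e$n_absence) / odds(r$n_persistent, r$n_absence)
    )
  )
}

#' Persistent-absence percentages from published aggregates
#'
#' @param aggregates Tibble as returned by [echild_outcome_aggregates()].
#' @return Tibble with per-arm and total persistent-absence percentages.
#' @export
persistent_percentages <- function(aggregates = echild_outcome_aggregates()) {
  tot <- tibble::tibble(
    treatment = "Total",
    pct = 100 * sum(aggregates$n_persistent) / sum(aggregates$n_absence)
  )
  dplyr::bind_rows(
    tibble::tibble(treatment = aggregates$treatment,
                   pct = 100 * aggregates$n_persistent / aggregates$n_absence),
    tot
  )
}
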