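# formula RHS over MCIM terms; declared-continuous covariates get a
# quadratic companion
build_rhs <- function(terms, quadratic = continuous_confounders()) {
  parts <- vapply(terms, function(v) {
    if (v %in% quadratic) paste0("`", v, "` + I(`", v, "`^2)") else paste0("`", v, "`")
  }, character(1))
  paste(parts, collapse = " + ")
}

# restrict an analysis table to a two-arm contrast, adding the exposure
# indicator .a (1 = exposed level)
restrict_contrast <- function(table, contrast) {
  exposed <- contrast[1]; reference <- contrast[2]
  stopifnot(all(c(exposed, reference) %in% levels(factor(table$treatment))))
  out <- table[table$treatment %in% c(exposed, reference), , drop = FALSE]
  if (!any(out$treatment == exposed) || !any(out$treatment == reference)) {
    stop("both contrast arms must be non-empty", call. = FALSE)
  }
  out$.a <- as.integer(out$treatment == exposed)
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.factor), droplevels))
  out
}

#' Fit a pairwise propensity-score model
#'
#' Binary logistic regression of the exposed level versus the reference
#' level on the MCIM-expanded confounder design, restricted to pupils
#' observed in one of the two compared arms. Continuous confounders enter
#' with linear and quadratic terms. Predicted probabilities of the exposed
#' level are attached, together with a PS-decile overlap table and a
#' positivity flag.
#'
#' @param table An analysis tibble (see [derive_analysis_table()]).
#' @param contrast `c(exposed, reference)` treatment levels.
#' @param covariates Model terms; default: all confounders plus
#'   missingness indicators ([apply_mcim()]).
#' @param quadratic Covariates entered with an added squared term.
#' @param min_per_cell Cell-count threshold for [positivity_check()].
#' @return Object of class `ps_fit`: the fitted model, the arm-restricted
#'   data with column `ps`, the overlap table and `pass`/`warn`/`fail`
#'   flag.
#' @export
fit_ps_model <- function(table, contrast = c("Support", "None"),
                         covariates = NULL,
                         quadratic = continuous_confounders(),
                         min_per_cell = 5) {
  table <- apply_mcim(table)
  if (is.null(covariates)) covariates <- attr(table, "mcim_terms")
  dat <- restrict_contrast(table, contrast)
  rhs <- if (length(covariates) == 0) "1" else build_rhs(covariates, quadratic)
  fml <- as.formula(paste(".a ~", rhs))
  fit <- glm(fml, data = dat, family = binomial(),
             control = list(epsilon = 1e-12, maxit = 100))
  p <- fitted(fit)
  if (!fit$converged || any(p <= 0) || any(p >= 1)) {
    cc <- coef(fit)[!is.na(coef(fit))]
    worst <- names(sort(abs(cc), decreasing = TRUE))[seq_len(min(3, length(cc)))]
    stop("propensity model separation / non-convergence; largest terms: ",
         paste(worst, collapse = ", "), call. = FALSE)
  }
  dat$ps <- p
  res <- structure(
    list(contrast = contrast, model = fit, data = dat,
         model_spec = list(covariates = covariates, quadratic = quadratic)),
    class = "ps_fit"
  )
  res$overlap <- overlap_summary(res)
  res$flag <- positivity_check(res$overlap$table, min_per_cell = min_per_cell)
  res
}

#' @export
print.ps_fit <- function(x, ...) {
  cat("<ps_fit> ", x$contrast[1], " vs ", x$contrast[2],
      "  (n = ", nrow(x$data), ")\n", sep = "")
  cat("  positivity: ", x$flag, "\n", sep = "")
  rng <- x$overlap$range
  cat(sprintf("  PS range exposed [%.3f, %.3f], reference [%.3f, %.3f]\n",
              rng$min[rng$arm == "exposed"], rng$max[rng$arm == "exposed"],
              rng$min[rng$arm == "reference"], rng$max[rng$arm == "reference"]))
  invisible(x)
}

#' Overlap diagnostics for a fitted propensity score
#'
#' Tabulates pupils per PS decile (pooled-sample quantile bins) and arm,
#' and summarises the per-arm PS range and the shared-support interval.
#'
#' @param ps_result A `ps_fit`, or a data frame with columns `ps` and `.a`.
#' @return List with `table` (decile x arm counts), `range` (per-arm
#'   min/max) and `shared_support` (intersection of arm ranges).
#' @export
overlap_summary <- function(ps_result) {
  dat <- if (inherits(ps_result, "ps_fit")) ps_result$data else ps_result
  brks <- unique(quantile(dat$ps, probs = 0:10 / 10, names = FALSE))
  if (length(brks) < 3) brks <- c(0, median(dat$ps), 1)
  dec <- cut(dat$ps, breaks = brks, include.lowest = TRUE)
  tab <- dat |>
    dplyr::mutate(decile = dec,
                  arm = ifelse(.data$.a == 1, "exposed", "reference")) |>
    dplyr::count(.data$decile, .data$arm) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "n", values_fill = 0L)
  for (cl in c("exposed", "reference")) if (!cl %in% names(tab)) tab[[cl]] <- 0L
  rng <- dat |>
    dplyr::mutate(arm = ifelse(.data$.a == 1, "exposed", "reference")) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(min = min(.data$ps), max = max(.data$ps), .groups = "drop")
  list(
    table = tab,
    range = rng,
    shared_support = c(max(rng$min), min(rng$max))
  )
}

#' Positivity gate from the overlap table
#'
#' `fail` if any PS decile holding at least `min_per_cell` pupils of one
#' arm holds zero of the other (structural lack of support); `warn` if
#' some decile has fewer than `min_per_cell` pupils in an arm; `pass`
#' otherwise.
#'
#' @param overlap_table Decile x arm counts (from [overlap_summary()]).
#' @param min_per_cell Minimum pupils per arm per decile (default 5).
#' @return `"pass"`, `"warn"` or `"fail"`.
#' @export
positivity_check <- function(overlap_table, min_per_cell = 5) {
  e <- overlap_table$exposed; r <- overlap_table$reference
  if (any((e >= min_per_cell & r == 0) | (r >= min_per_cell & e == 0))) {
    return("fail")
  }
  if (any(e < min_per_cell | r < min_per_cell)) return("warn")
  "pass"
}

#' Lasso covariate selection for nuisance models
#'
#' Cross-validated lasso on the standardised design; returns the
#' covariates with non-zero coefficients at the penalty minimising CV
#' deviance. Forced terms (e.g. the treatment indicator in outcome
#' models) carry zero penalty and are always returned. Downstream callers
#' refit unpenalised on the selected set (post-lasso).
#'
#' @param design Numeric model matrix (no intercept column).
#' @param response Response vector matching `family`.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param n_folds CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param force Column names always retained (penalty 0).
#' @param offset Optional log-exposure offset (count families).
#' @return Character vector of selected column names.
#' @export
lasso_select <- function(design, response, family = "gaussian",
                         n_folds = 10, seed = 1, force = character(),
                         offset = NULL) {
  stopifnot(family %in% c("gaussian", "binomial", "poisson"))
  keep <- complete.cases(design, response)
  design <- design[keep, , drop = FALSE]
  response <- response[keep]
  if (!is.null(offset)) offset <- offset[keep]
  pf <- ifelse(colnames(design) %in% force, 0, 1)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), nrow(design)))
  cv <- glmnet::cv.glmnet(design, response, family = family,
                          foldid = foldid, penalty.factor = pf,
                          offset = offset)
  b <- coef(cv, s = "lambda.min")
  sel <- rownames(b)[as.vector(b != 0)]
  sel <- setdiff(sel, "(Intercept)")
  sel <- union(intersect(colnames(design), sel), intersect(colnames(design), force))
  if (length(setdiff(sel, force)) == 0 && length(sel) == 0) {
    warning("lasso selected no covariates; falling back to forced terms only")
  }
  sel
}
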