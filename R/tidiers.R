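#' Tidy a fitted propensity-score model
#'
#' Coefficient-level summary of the underlying logistic fit.
#'
#' @param x A `ps_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @exportS3Method generics::tidy
tidy.ps_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @rdname tidy.ps_fit
#' @exportS3Method generics::glance
glance.ps_fit <- function(x, ...) {
  tibble::tibble(
    contrast = paste(x$contrast[1], "vs", x$contrast[2]),
    n = nrow(x$data),
    n_exposed = sum(x$data$.a),
    positivity = x$flag,
    support_low = x$overlap$shared_support[1],
    support_high = x$overlap$shared_support[2],
    mean_ps = mean(x$data$ps)
  )
}

#' Propensity-score overlap plot
#'
#' Density of the fitted propensity score by observed arm, the visual
#' positivity diagnostic.
#'
#' @param object A `ps_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ps_fit <- function(object, ...) {
  d <- object$data
  d$arm <- ifelse(d$.a == 1, object$contrast[1], object$contrast[2])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ps, fill = .data$arm)) +
    ggplot2::geom_density(alpha = 0.45, colour = NA) +
    ggplot2::labs(
      x = paste0("P(", object$contrast[1], " | confounders)"),
      y = "density", fill = "observed arm",
      title = paste("Propensity overlap:", object$contrast[1], "vs",
                    object$contrast[2]),
      subtitle = paste("positivity:", object$flag)
    ) +
    ggplot2::theme_minimal()
}

#' Tidy pipeline results
#'
#' @param x A `tte_results` bundle.
#' @param ... Unused.
#' @return The long estimates tibble (one row per outcome x estimand x
#'   estimator).
#' @exportS3Method generics::tidy
tidy.tte_results <- function(x, ...) {
  dplyr::select(x$estimates, -dplyr::any_of("diagnostics"))
}

#' @rdname tidy.tte_results
#' @exportS3Method generics::glance
glance.tte_results <- function(x, ...) {
  dplyr::mutate(x$positivity,
                B = x$settings$B, seed = x$settings$seed)
}

#' Forest plot of estimated effects
#'
#' Points and bootstrap intervals per outcome, estimand and estimator;
#' ratio measures are drawn on a log scale with a null line at 1, mean
#' differences on a linear scale with a null line at 0.
#'
#' @param object A `tte_results` bundle.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tte_results <- function(object, ...) {
  est <- dplyr::filter(object$estimates, .data$estimand %in% c("ATE", "ATT"))
  est$ratio <- est$measure %in% c("RaR", "RiR", "OR")
  est$y <- paste(est$outcome, est$estimand)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate, y = .data$y,
                                    colour = .data$estimator)) +
    ggplot2::geom_vline(data = data.frame(ratio = c(TRUE, FALSE),
                                          x = c(1, 0)),
                        ggplot2::aes(xintercept = .data$x),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~ratio, scales = "free_x",
                        labeller = ggplot2::labeller(
                          ratio = c(`TRUE` = "ratio scale",
                                    `FALSE` = "difference scale"))) +
    ggplot2::labs(x = "estimate", y = NULL, colour = "estimator") +
    ggplot2::theme_minimal()
}

#' @rdname cluster_bootstrap
#' @param x A `boot_ci`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.boot_ci <- function(x, ...) x$summary

#' @rdname cluster_bootstrap
#' @exportS3Method generics::glance
glance.boot_ci <- function(x, ...) {
  tibble::tibble(B = x$B, n_failed = x$n_failed, seed = x$seed,
                 interval = x$interval)
}
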