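#' Cluster bootstrap for any estimator chain
#'
#' Resamples clusters (home local authorities) with replacement -- the
#' same number of clusters as observed -- concatenates all pupils of the
#' sampled clusters (repeated clusters are relabelled as distinct), and
#' re-runs the supplied estimator closure on each replicate, so nuisance
#' models (the propensity fit included) are refit inside every replicate.
#' Intervals are percentile by default: the bounds are order statistics
#' of the replicate set.
#'
#' @param table Analysis tibble with a cluster column.
#' @param statistic Function mapping a table to a named numeric vector of
#'   point estimates (one or many).
#' @param B Number of replicates (reports use 1000; tests 199).
#' @param seed Integer seed; same seed and B give identical intervals.
#' @param cluster Cluster column name.
#' @param interval `"percentile"` (default) or `"normal"` (point estimate
#'   from the full table plus-minus 1.96 bootstrap SE).
#' @return Object of class `boot_ci`: `replicates` (B x terms tibble),
#'   `summary` (term, se, ci_low, ci_high), `n_failed`, `B`, `seed`.
#' @export
cluster_bootstrap <- function(table, statistic, B = 1000, seed = 1,
                              cluster = "cluster_id",
                              interval = c("percentile", "normal")) {
  interval <- match.arg(interval)
  stopifnot(B >= 1, cluster %in% names(table))
  rows <- split(seq_len(nrow(table)), table[[cluster]])
  G <- length(rows)
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    pick <- sample.int(G, G, replace = TRUE)
    idx <- unlist(rows[pick], use.names = FALSE)
    dat <- table[idx, , drop = FALSE]
    dat[[cluster]] <- rep(seq_len(G), lengths(rows)[pick])
    reps[[b]] <- tryCatch(statistic(dat), error = function(e) NULL)
  }
  ok <- !vapply(reps, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * B) {
    stop(n_failed, " of ", B, " bootstrap replicates failed (> 5%)",
         call. = FALSE)
  }
  mat <- do.call(rbind, reps[ok])
  if (is.null(colnames(mat))) colnames(mat) <- paste0("stat", seq_len(ncol(mat)))
  summ <- purrr::map_dfr(colnames(mat), function(tm) {
    x <- mat[, tm]
    if (interval == "percentile") {
      qs <- quantile(x, c(0.025, 0.975), type = 1, names = FALSE, na.rm = TRUE)
    } else {
      ctr <- mean(x, na.rm = TRUE)
      qs <- ctr + c(-1, 1) * 1.96 * sd(x, na.rm = TRUE)
    }
    tibble::tibble(term = tm, se = sd(x, na.rm = TRUE),
                   ci_low = qs[1], ci_high = qs[2])
  })
  structure(list(replicates = tibble::as_tibble(mat), summary = summ,
                 n_failed = n_failed, B = B, seed = seed,
                 interval = interval),
            class = "boot_ci")
}

#' @export
print.boot_ci <- function(x, ...) {
  cat("<boot_ci> B = ", x$B, ", failed = ", x$n_failed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Cluster-robust (sandwich) standard errors
#'
#' Sandwich variance aggregating score contributions by cluster, with the
#' usual small-sample factor G/(G-1) (G = number of clusters). Built on
#' `sandwich::vcovCL`.
#'
#' @param fit A fitted `lm`/`glm` model.
#' @param cluster_id Cluster membership vector, aligned with the model
#'   frame rows.
#' @return Named vector of standard errors, one per coefficient.
#' @export
cluster_robust_se <- function(fit, cluster_id) {
  G <- length(unique(cluster_id))
  if (G < 2) stop("need at least 2 clusters", call. = FALSE)
  V <- sandwich::vcovCL(fit, cluster = cluster_id, type = "HC0",
                        cadjust = TRUE)
  sqrt(diag(V))
}
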