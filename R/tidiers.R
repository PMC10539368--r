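# broom-style accessors for fitted objects.

#' Tidy a mixed-model fit
#'
#' @param x A `bq_mixed_fit` from [fit_binomial_glmm()] or
#'   [fit_linear_mixed()].
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term: `term`,
#'   `estimate`, `std.error`, `statistic`.
#' @export
tidy.bq_mixed_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = unname(x$coefficients / x$se))
}

#' Model-level summary of a mixed-model fit
#'
#' @inheritParams tidy.bq_mixed_fit
#' @return A one-row tibble: `model`, `sigma_cluster` (between-animal
#'   SD), `residual_sd` (linear model only), `logLik`, `nobs`,
#'   `n_clusters`, `boundary`.
#' @export
glance.bq_mixed_fit <- function(x, ...) {
  tibble(model = x$model, sigma_cluster = x$sigma,
         residual_sd = if (x$model == "linear") x$tau else NA_real_,
         logLik = x$logLik, nobs = x$nobs, n_clusters = x$n_clusters,
         boundary = x$boundary)
}

#' Tidy a parametric bootstrap result
#'
#' @param x A `bq_boot` from [parametric_bootstrap_test()].
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `p_value`, `B`, `B_used`,
#'   `n_dropped`.
#' @export
tidy.bq_boot <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         B = x$B, B_used = x$B_used, n_dropped = x$n_dropped)
}

#' @export
print.bq_mixed_fit <- function(x, ...) {
  kind <- if (x$model == "binomial") {
    "Random-intercept logistic mixed model (ML, adaptive Gauss-Hermite)"
  } else {
    "Random-intercept linear mixed model (ML)"
  }
  cat(kind, "\n")
  cat(sprintf("  groups: %s (reference) vs %s\n",
              x$group_levels[1], x$group_levels[2]))
  cat(sprintf("  beta = %.3f (se %.3f), sigma_animal = %.3f%s\n",
              x$coefficients["group"], x$se["group"], x$sigma,
              if (x$boundary) " [boundary]" else ""))
  cat(sprintf("  logLik %.2f on %d obs in %d clusters\n",
              x$logLik, x$nobs, x$n_clusters))
  invisible(x)
}

#' @export
print.bq_boot <- function(x, ...) {
  cat(sprintf(
    "Parametric bootstrap LR test: stat = %.3f, p = %.4g (B = %d, used %d)\n",
    x$statistic, x$p_value, x$B, x$B_used))
  invisible(x)
}
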