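# Inferential machinery for animal-clustered outcomes: pooled log-odds,
# random-intercept logistic and linear mixed models fit by maximum
# likelihood (adaptive Gauss-Hermite quadrature for the logistic model),
# likelihood-ratio parametric bootstrap tests, and Welch-t utilities with
# multiplicity correction.

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

lor_from_prop <- function(p1, p0) {
  log((p1 / (1 - p1)) / (p0 / (1 - p0)))
}

#' Pooled log-odds ratio of a binary outcome between two groups
#'
#' Ignores clustering and compares pooled proportions:
#' `ln[(p1/(1-p1)) / (p0/(1-p0))]`, the closed-form companion to the
#' mixed-model fixed effect (the two coincide when the between-animal SD
#' is zero). Degenerate pooled proportions (0 or 1) receive a
#' Haldane-Anscombe continuity correction (+0.5 per cell) with a warning.
#'
#' @param data Long tibble with one row per neuron.
#' @param outcome,group Column names of the 0/1 outcome and the group
#'   factor (first level = reference).
#' @return A one-row tibble with `lor`, the group proportions `p_ref` /
#'   `p_alt`, and counts.
#' @export
pooled_log_odds <- function(data, outcome = "outcome", group = "group") {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("`group` must have exactly two levels.")
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) abort("`outcome` must be binary 0/1.")
  n <- tapply(y, g, length)
  k <- tapply(y, g, sum)
  if (any(k == 0 | k == n)) {
    warn("Degenerate pooled proportion; continuity correction (+0.5) applied.")
    p <- (k + 0.5) / (n + 1)
  } else {
    p <- k / n
  }
  tibble(lor = unname(lor_from_prop(p[2], p[1])),
         p_ref = unname(k[1] / n[1]), p_alt = unname(k[2] / n[2]),
         n_ref = unname(n[1]), n_alt = unname(n[2]))
}

# Collapse a long (animal, group, outcome) table to cluster summaries.
cluster_summaries <- function(data, outcome, group, cluster) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("`group` must have exactly two levels.")
  df <- tibble(cluster = as.character(data[[cluster]]),
               x = as.numeric(g) - 1, y = data[[outcome]])
  agg <- dplyr::summarise(dplyr::group_by(df, .data$cluster),
                          x = .data$x[1], n = dplyr::n(),
                          y = sum(.data$y), .groups = "drop")
  if (any(tapply(df$x, df$cluster, function(v) length(unique(v))) > 1)) {
    abort("Each animal must belong to a single group.")
  }
  list(agg = agg, levels = levels(g))
}

glmm_core <- function(agg, include_group, nagq, start = NULL) {
  gh <- pracma::gaussHermite(nagq)
  npar <- if (include_group) 3L else 2L
  if (is.null(start)) {
    # continuity-corrected pooled log-odds as starting values
    p0 <- (sum(agg$y[agg$x == 0]) + 0.5) / (sum(agg$n[agg$x == 0]) + 1)
    if (include_group) {
      p1 <- (sum(agg$y[agg$x == 1]) + 0.5) / (sum(agg$n[agg$x == 1]) + 1)
      start <- c(qlogis(p0), qlogis(p1) - qlogis(p0), log(0.5))
    } else {
      pa <- (sum(agg$y) + 0.5) / (sum(agg$n) + 1)
      start <- c(qlogis(pa), log(0.5))
    }
  }
  nll <- function(par) {
    glmm_agq_nll(par, agg$x, agg$n, agg$y, gh$x, gh$w, include_group)
  }
  lo <- c(rep(-Inf, npar - 1), log(1e-6))
  hi <- c(rep(Inf, npar - 1), log(50))
  opt <- nlminb(start, nll, lower = lo, upper = hi)
  if (!opt$convergence %in% c(0, 1)) {
    abort(sprintf("GLMM did not converge (nlminb code %d: %s).",
                  opt$convergence, opt$message))
  }
  sigma <- exp(opt$par[npar])
  list(par = opt$par, logLik = -opt$objective, sigma = sigma,
       boundary = sigma <= 1e-5, nll = nll, npar = npar)
}

#' Random-intercept logistic mixed model (ML, adaptive Gauss-Hermite)
#'
#' Fits `outcome ~ Bernoulli(logit^-1(b0 + beta * group + u_animal))`,
#' `u_animal ~ N(0, sigma^2)`, by maximum likelihood with the marginal
#' likelihood integrated per animal by adaptive Gauss-Hermite quadrature
#' (25 nodes by default, posterior-mode centering per animal). The
#' neuron-level rows with animal clusters are the modeling unit; the only
#' fixed covariate is the (animal-level) group. Standard errors come from
#' the observed information of the fixed effects at the optimum (variance
#' held at its MLE). A variance estimate on the boundary (sigma ~ 0, at
#' which point the model collapses to ordinary logistic regression) is
#' flagged, not an error.
#'
#' @param data Long tibble, one row per neuron.
#' @param outcome,group,cluster Column names (0/1 outcome; two-level
#'   group, first level reference; animal id).
#' @param nagq Number of quadrature nodes.
#' @return An object of classes `bq_glmm` / `bq_mixed_fit` with elements
#'   `coefficients` (intercept, beta), `se`, `sigma`, `logLik`,
#'   `null_logLik`, `boundary`, and the cluster summaries used.
#' @export
fit_binomial_glmm <- function(data, outcome = "outcome", group = "group",
                              cluster = "animal", nagq = 25) {
  cs <- cluster_summaries(data, outcome, group, cluster)
  agg <- cs$agg
  fit <- glmm_core(agg, include_group = TRUE, nagq = nagq)
  fit0 <- glmm_core(agg, include_group = FALSE, nagq = nagq)
  hess <- tryCatch(
    stats::optimHess(fit$par[1:2], function(fx) fit$nll(c(fx, log(fit$sigma)))),
    error = function(e) NULL
  )
  se <- if (is.null(hess)) rep(NA_real_, 2) else {
    vc <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, 2, 2))
    sqrt(pmax(diag(vc), 0))
  }
  structure(
    list(
      coefficients = setNames(fit$par[1:2], c("(Intercept)", "group")),
      se = setNames(se, c("(Intercept)", "group")),
      sigma = fit$sigma, logLik = fit$logLik, null_logLik = fit0$logLik,
      boundary = fit$boundary, nagq = nagq, agg = agg,
      group_levels = cs$levels, model = "binomial",
      nobs = sum(agg$n), n_clusters = nrow(agg)
    ),
    class = c("bq_glmm", "bq_mixed_fit")
  )
}

# ML fit of the compound-symmetry model with the fixed effects profiled
# out by closed-form GLS at each variance setting: the cluster-level
# weight is n_i / (tau^2 + n_i sigma^2), so only (log sigma, log tau) are
# optimized numerically.
lmm_ml <- function(agg_list, include_group) {
  p_fixed <- if (include_group) 2L else 1L
  gls <- function(s2, t2) {
    A <- matrix(0, p_fixed, p_fixed)
    bv <- numeric(p_fixed)
    for (cl in agg_list) {
      n <- length(cl$y)
      w <- n / (t2 + n * s2)
      xi <- if (include_group) c(1, cl$x) else 1
      A <- A + w * tcrossprod(xi)
      bv <- bv + xi * w * mean(cl$y)
    }
    list(beta = solve(A, bv), A = A)
  }
  nll_at <- function(s2, t2, beta) {
    nll <- 0
    for (cl in agg_list) {
      mu <- beta[1] + (if (include_group) beta[2] * cl$x else 0)
      e <- cl$y - mu
      n <- length(e)
      quad <- (sum(e^2) - s2 / (t2 + n * s2) * sum(e)^2) / t2
      logdet <- (n - 1) * log(t2) + log(t2 + n * s2)
      nll <- nll + 0.5 * (n * log(2 * pi) + logdet + quad)
    }
    nll
  }
  obj <- function(p) {
    s2 <- exp(2 * p[1]); t2 <- exp(2 * p[2])
    nll_at(s2, t2, gls(s2, t2)$beta)
  }
  all_y <- unlist(lapply(agg_list, `[[`, "y"))
  sd0 <- max(sd(all_y), 1e-3)
  opt <- nlminb(c(log(sd0 / 2), log(sd0 / 2)), obj,
                lower = log(1e-6), upper = log(1e6 * sd0))
  if (!opt$convergence %in% c(0, 1)) {
    abort(sprintf("LMM did not converge (nlminb code %d).", opt$convergence))
  }
  s2 <- exp(2 * opt$par[1]); t2 <- exp(2 * opt$par[2])
  g <- gls(s2, t2)
  vc <- solve(g$A)
  list(beta = g$beta, se = sqrt(diag(vc)), sigma = sqrt(s2), tau = sqrt(t2),
       logLik = -opt$objective)
}

#' Random-intercept linear mixed model (ML)
#'
#' Fits `outcome = b0 + beta * group + u_animal + e`, `u ~ N(0, sigma^2)`,
#' `e ~ N(0, tau^2)`, by maximum likelihood using the closed-form
#' compound-symmetry likelihood per animal. A between-animal variance on
#' the boundary is flagged singular.
#'
#' @inheritParams fit_binomial_glmm
#' @return An object of classes `bq_lmm` / `bq_mixed_fit` with
#'   `coefficients`, `se`, `sigma` (between-animal SD), `tau` (residual
#'   SD), `logLik`, `null_logLik`, `boundary`.
#' @export
fit_linear_mixed <- function(data, outcome = "outcome", group = "group",
                             cluster = "animal") {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("`group` must have exactly two levels.")
  df <- tibble(cluster = as.character(data[[cluster]]),
               x = as.numeric(g) - 1, y = data[[outcome]])
  agg_list <- lapply(split(df, df$cluster), function(d) {
    if (length(unique(d$x)) > 1) abort("Each animal must belong to one group.")
    list(x = d$x[1], y = d$y)
  })
  fit <- lmm_ml(agg_list, include_group = TRUE)
  fit0 <- lmm_ml(agg_list, include_group = FALSE)
  if (fit$sigma <= 1e-5) {
    warn("Between-animal variance on the boundary; fit is singular.")
  }
  structure(
    list(
      coefficients = setNames(unname(fit$beta), c("(Intercept)", "group")),
      se = setNames(unname(fit$se), c("(Intercept)", "group")),
      sigma = unname(fit$sigma), tau = unname(fit$tau), logLik = fit$logLik,
      null_logLik = fit0$logLik, boundary = fit$sigma <= 1e-5,
      agg = lapply(agg_list, function(a) list(x = a$x, n = length(a$y))),
      null_pars = c(b0 = unname(fit0$beta[1]), sigma = unname(fit0$sigma),
                    tau = unname(fit0$tau)),
      group_levels = levels(g), model = "linear",
      nobs = nrow(df), n_clusters = length(agg_list)
    ),
    class = c("bq_lmm", "bq_mixed_fit")
  )
}

# Fit the alternative and null models to a simulated replicate and return
# the likelihood-ratio statistic, or NA on failure.
boot_stat <- function(fit, sim) {
  tryCatch({
    if (fit$model == "binomial") {
      agg <- fit$agg
      agg$y <- sim
      a <- glmm_core(agg, TRUE, fit$nagq)
      n0 <- glmm_core(agg, FALSE, fit$nagq)
      max(0, 2 * (a$logLik - n0$logLik))
    } else {
      data <- sim  # tibble(animal, group, outcome)
      f <- fit_linear_mixed(data)
      max(0, 2 * (f$logLik - f$null_logLik))
    }
  }, error = function(e) NA_real_)
}

#' Parametric bootstrap test of the group effect
#'
#' Tests the fixed group effect of a [fit_binomial_glmm()] /
#' [fit_linear_mixed()] fit by a likelihood-ratio parametric bootstrap:
#' `B` datasets are simulated from the fitted *null* model (group effect
#' removed, random intercepts redrawn), both models are refit to each
#' replicate, and `p = (1 + #\{LR* >= LR_obs\}) / (B + 1)`. The smallest
#' attainable p-value is `1 / (B + 1)` — e.g. 0.0002 at `B = 4999` and
#' 0.001 at `B = 999` — and the test never returns zero. Replicates whose
#' refit fails are dropped and counted (warning beyond 5%).
#'
#' @param fit A `bq_mixed_fit`.
#' @param B Number of bootstrap replicates (default 4999 for the
#'   logistic model, 999 for the linear model).
#' @param seed Integer RNG seed.
#' @return A list of class `bq_boot`: `p_value`, `statistic` (observed
#'   LR), `B`, `B_used`, `n_dropped`.
#' @export
parametric_bootstrap_test <- function(fit, B = NULL, seed = 1L) {
  if (!inherits(fit, "bq_mixed_fit")) abort("`fit` must be a bq_mixed_fit.")
  B <- B %||% if (fit$model == "binomial") 4999L else 999L
  stat_obs <- max(0, 2 * (fit$logLik - fit$null_logLik))
  stats_star <- with_local_seed(seed, {
    if (fit$model == "binomial") {
      agg <- fit$agg
      null_fit <- glmm_core(agg, FALSE, fit$nagq)
      b0 <- null_fit$par[1]
      sig0 <- null_fit$sigma
      vapply(seq_len(B), function(b) {
        u <- rnorm(nrow(agg), 0, sig0)
        boot_stat(fit, rbinom(nrow(agg), agg$n, plogis(b0 + u)))
      }, numeric(1))
    } else {
      clusters <- fit$agg
      null_pars <- fit$null_pars
      vapply(seq_len(B), function(b) {
        sim <- purrr::map_dfr(seq_along(clusters), function(i) {
          cl <- clusters[[i]]
          u <- rnorm(1, 0, null_pars["sigma"])
          tibble(animal = sprintf("c%03d", i),
                 group = factor(ifelse(cl$x == 1, "g1", "g0"),
                                levels = c("g0", "g1")),
                 outcome = null_pars["b0"] + u +
                   rnorm(cl$n, 0, null_pars["tau"]))
        })
        boot_stat(fit, sim)
      }, numeric(1))
    }
  })
  ok <- !is.na(stats_star)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.05 * B) {
    warn(sprintf("%d of %d bootstrap replicates dropped (non-convergence).",
                 n_dropped, B))
  }
  B_used <- sum(ok)
  p <- (1 + sum(stats_star[ok] >= stat_obs)) / (B_used + 1)
  structure(list(p_value = p, statistic = stat_obs, B = B,
                 B_used = B_used, n_dropped = n_dropped),
            class = "bq_boot")
}

#' Welch's t tests with Holm or Benjamini-Hochberg correction
#'
#' Two-sided Welch (unequal-variance) t tests with Satterthwaite degrees
#' of freedom, corrected across the stated family: either one test per
#' level of `family` comparing the two groups (e.g. per cortical layer),
#' or all pairwise group comparisons when `family` is `NULL` and the
#' group has more than two levels.
#'
#' @param data Long tibble.
#' @param value,group Column names of the response and the group factor.
#' @param family Optional column defining the correction family.
#' @param correction `"holm"` (default) or `"bh"`.
#' @return A tibble with one row per comparison: group labels (and
#'   family level), `estimate` (difference of means), `statistic`, `df`,
#'   `p_value`, `p_adjusted`; comparisons with zero variance in both
#'   groups are `NA` and flagged in `undefined`.
#' @export
welch_holm <- function(data, value = "value", group = "group",
                       family = NULL, correction = c("holm", "bh")) {
  correction <- match.arg(correction)
  method <- if (correction == "bh") "BH" else "holm"
  g <- factor(data[[group]])
  run_test <- function(v1, v2) {
    if ((length(unique(v1)) < 2 && length(unique(v2)) < 2) ||
        (sd(v1) == 0 && sd(v2) == 0)) {
      return(list(estimate = mean(v2) - mean(v1), statistic = NA_real_,
                  df = NA_real_, p = NA_real_, undefined = TRUE))
    }
    tt <- t.test(v2, v1, var.equal = FALSE)
    list(estimate = mean(v2) - mean(v1),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, undefined = FALSE)
  }
  rows <- if (!is.null(family)) {
    if (nlevels(g) != 2) abort("`family` mode needs exactly two groups.")
    fam <- factor(data[[family]])
    purrr::map_dfr(levels(fam), function(fl) {
      sel <- fam == fl
      r <- run_test(data[[value]][sel & g == levels(g)[1]],
                    data[[value]][sel & g == levels(g)[2]])
      tibble(family = fl, group1 = levels(g)[1], group2 = levels(g)[2],
             estimate = r$estimate, statistic = r$statistic, df = r$df,
             p_value = r$p, undefined = r$undefined)
    })
  } else {
    prs <- utils::combn(levels(g), 2, simplify = FALSE)
    purrr::map_dfr(prs, function(pr) {
      r <- run_test(data[[value]][g == pr[1]], data[[value]][g == pr[2]])
      tibble(group1 = pr[1], group2 = pr[2], estimate = r$estimate,
             statistic = r$statistic, df = r$df, p_value = r$p,
             undefined = r$undefined)
    })
  }
  rows$p_adjusted <- p.adjust(rows$p_value, method = method)
  rows
}
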