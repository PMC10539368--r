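# Mixed models, bootstrap machinery, pooled log-odds, Welch utilities.

test_that("pooled log-odds reproduces the closed forms", {
  make_counts <- function(p0, p1, n = 100) {
    rbind(
      data.frame(animal = "a", group = "control",
                 outcome = rep(c(1, 0), c(round(p0 * n), n - round(p0 * n)))),
      data.frame(animal = "b", group = "mutant",
                 outcome = rep(c(1, 0), c(round(p1 * n), n - round(p1 * n))))
    )
  }
  # 42% vs 89% pyramidal -> 2.41 to two decimals
  expect_equal(round(pooled_log_odds(make_counts(0.42, 0.89))$lor, 2), 2.41)
  # 42% vs 94% -> 3.07
  expect_equal(round(pooled_log_odds(make_counts(0.42, 0.94))$lor, 2), 3.07)
  expect_equal(pooled_log_odds(make_counts(0.3, 0.3))$lor, 0)
  expect_warning(cc <- pooled_log_odds(make_counts(0.42, 1)), "continuity")
  expect_true(is.finite(cc$lor))
})

test_that("the GLMM collapses to logistic regression when sigma is zero", {
  tab <- simulate_morphology(n_animals = c(30, 30), neurons_per_animal = 30,
                             beta = 1.5, sigma = 0, baseline = -0.5, seed = 41)
  fit <- fit_binomial_glmm(tab)
  glm_fit <- glm(outcome ~ group, family = binomial(), data = tab)
  expect_lt(abs(coef(fit)["group"] - coef(glm_fit)[2]), 1e-3)
  plo <- pooled_log_odds(tab)
  expect_lt(abs(coef(fit)["group"] - plo$lor), 1e-3)
})

test_that("the GLMM agrees with an independent AGQ implementation (lme4)", {
  library(lme4)
  tab <- simulate_morphology(n_animals = c(10, 8), neurons_per_animal = 15,
                             beta = 2.4, sigma = 0.5, seed = 42)
  ours <- fit_binomial_glmm(tab)
  ref <- glmer(outcome ~ group + (1 | animal), data = tab,
               family = binomial(), nAGQ = 25)
  expect_equal(unname(coef(ours)["group"]), unname(fixef(ref)[2]),
               tolerance = 1e-4)
  expect_equal(ours$sigma, sqrt(unlist(VarCorr(ref))[[1]]), tolerance = 1e-3)
  expect_equal(unname(coef(ours)["(Intercept)"]), unname(fixef(ref)[1]),
               tolerance = 1e-4)
})

test_that("quadrature is stable to doubling the node count", {
  tab <- simulate_morphology(n_animals = c(8, 8), neurons_per_animal = 12,
                             beta = 2, sigma = 0.6, seed = 43)
  f25 <- fit_binomial_glmm(tab, nagq = 25)
  f50 <- fit_binomial_glmm(tab, nagq = 50)
  expect_lt(abs(coef(f25)["group"] - coef(f50)["group"]), 1e-4)
})

test_that("swapping group labels negates the fixed effect", {
  tab <- simulate_morphology(n_animals = c(6, 6), neurons_per_animal = 10,
                             beta = 1.8, sigma = 0.4, seed = 44)
  swapped <- tab
  swapped$group <- factor(tab$group, levels = rev(levels(tab$group)))
  f1 <- fit_binomial_glmm(tab)
  f2 <- fit_binomial_glmm(swapped)
  expect_equal(unname(coef(f1)["group"]), -unname(coef(f2)["group"]),
               tolerance = 1e-5)
  # mixed-model log-likelihood dominates the sigma = 0 logistic fit
  glm_ll <- as.numeric(logLik(glm(cbind(y, n - y) ~ x, family = binomial(),
                                  data = f1$agg))) -
    sum(lchoose(f1$agg$n, f1$agg$y))  # drop the constant we also drop
  expect_gte(f1$logLik, glm_ll - 1e-8)
})

test_that("the linear mixed model matches lme4 and its degenerate limits", {
  library(lme4)
  cv <- simulate_clustered_values(n_animals = c(3, 3),
                                  sections_per_animal = 6,
                                  beta = 21.1, sigma = 3.78, tau = 3,
                                  seed = 45)
  ours <- fit_linear_mixed(cv)
  ref <- lmer(outcome ~ group + (1 | animal), data = cv, REML = FALSE)
  expect_equal(unname(coef(ours)["group"]), unname(fixef(ref)[2]),
               tolerance = 1e-4)
  expect_equal(ours$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
  vc <- as.data.frame(VarCorr(ref))$sdcor
  expect_equal(unname(c(ours$sigma, ours$tau)), vc, tolerance = 1e-3)
  # zero between-animal variance -> beta equals the difference of means
  flat <- simulate_clustered_values(n_animals = c(4, 4), sigma = 0, tau = 2,
                                    beta = 7, seed = 46)
  f0 <- suppressWarnings(fit_linear_mixed(flat))
  dm <- diff(tapply(flat$outcome, flat$group, mean))
  expect_lt(abs(coef(f0)["group"] - dm), 1e-6)
  # label-swap antisymmetry
  sw <- flat
  sw$group <- factor(flat$group, levels = rev(levels(flat$group)))
  f_sw <- suppressWarnings(fit_linear_mixed(sw))
  expect_equal(unname(coef(f0)["group"]), -unname(coef(f_sw)["group"]),
               tolerance = 1e-6)
})

test_that("bootstrap p-values have 1/(B+1) granularity and never reach zero", {
  tab <- simulate_morphology(n_animals = c(6, 6), neurons_per_animal = 20,
                             beta = 4, sigma = 0.3, seed = 47)
  fit <- fit_binomial_glmm(tab)
  bt <- parametric_bootstrap_test(fit, B = 99, seed = 48)
  expect_gt(bt$p_value, 0)
  expect_equal((bt$p_value * (bt$B_used + 1)) %% 1, 0, tolerance = 1e-12)
  # an overwhelming effect sits at the floor
  expect_equal(bt$p_value, 1 / (bt$B_used + 1))
  # a null effect gives an unremarkable p
  tab0 <- simulate_morphology(n_animals = c(6, 6), neurons_per_animal = 20,
                              beta = 0, sigma = 0.3, seed = 49)
  bt0 <- parametric_bootstrap_test(fit_binomial_glmm(tab0), B = 99, seed = 50)
  expect_gt(bt0$p_value, 0.05)
})

test_that("Welch tests match the textbook formulas and corrections", {
  a <- c(1, 2, 3, 4, 5); b <- c(6, 7, 8, 9, 10)
  dat <- data.frame(value = c(a, b), group = rep(c("g1", "g2"), each = 5))
  got <- welch_holm(dat)
  orc <- oracle_welch(b, a)
  expect_equal(got$statistic, orc$t, tolerance = 1e-10)
  expect_equal(got$df, orc$df, tolerance = 1e-10)
  expect_equal(got$p_value, orc$p, tolerance = 1e-12)
  # identical groups -> p = 1 after correction
  same <- data.frame(value = rep(c(1, 2, 3), 2),
                     group = rep(c("g1", "g2"), each = 3))
  expect_equal(welch_holm(same)$p_adjusted, 1)
  # Holm's first step multiplies the smallest p by the family size
  set.seed(51)
  fam <- dplyr::bind_rows(
    data.frame(layer = "L4", value = c(rnorm(8), rnorm(8, 6)),
               group = rep(c("a", "b"), each = 8)),
    data.frame(layer = "L5a", value = c(rnorm(8), rnorm(8, 0.1)),
               group = rep(c("a", "b"), each = 8)),
    data.frame(layer = "L5b", value = c(rnorm(8), rnorm(8, 0.05)),
               group = rep(c("a", "b"), each = 8))
  )
  res <- welch_holm(fam, family = "layer")
  i <- which.min(res$p_value)
  expect_equal(res$p_adjusted[i], min(3 * res$p_value[i], 1))
  # BH is the other supported family correction
  res_bh <- welch_holm(fam, family = "layer", correction = "bh")
  expect_equal(res_bh$p_adjusted,
               p.adjust(res_bh$p_value, "BH"))
  # zero variance in both groups is flagged, not an error
  const <- data.frame(value = rep(1, 6), group = rep(c("g1", "g2"), each = 3))
  expect_true(welch_holm(const)$undefined)
})

test_that("tidy and glance expose the fit in broom form", {
  tab <- simulate_morphology(n_animals = c(5, 5), neurons_per_animal = 12,
                             beta = 2, sigma = 0.3, seed = 52)
  fit <- fit_binomial_glmm(tab)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "group"))
  expect_equal(td$estimate, unname(coef(fit)))
  gl <- glance(fit)
  expect_equal(gl$sigma_cluster, fit$sigma)
  expect_equal(gl$n_clusters, 10)
  bt <- parametric_bootstrap_test(fit, B = 19, seed = 53)
  expect_equal(tidy(bt)$p_value, bt$p_value)
})
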