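test_that("volume log transform applies the epsilon floor", {
  expect_equal(log_transform_volume(0, 0.024), log(0.024), tolerance = 1e-12)
  expect_equal(log_transform_volume(0, 0.024), -3.7297, tolerance = 1e-4)
  eps <- 1e-12
  expect_equal(log_transform_volume(exp(1) - eps, eps), 1)
  v <- seq(0, 40, by = 0.5)
  expect_true(all(diff(log_transform_volume(v)) > 0))
  expect_error(log_transform_volume(-1), "non-negative")
})

test_that("noise-free data generated from the model is interpolated exactly", {
  n <- 12
  d <- expand.grid(subject_id = seq_len(n), visit_year = 0:3)
  set.seed(4)
  logv <- rnorm(n, 2, 1); age <- rnorm(n, 74, 5)
  d$logV <- logv[d$subject_id]; d$age <- age[d$subject_id]
  d$y <- 2 + 0.5 * d$logV - 0.1 * d$visit_year +
    0.05 * d$logV * d$visit_year + 0.01 * d$age
  fit <- suppressWarnings(wml_lmm(y ~ logV * visit_year + age, d,
                                  control = list(maxit = 50)))
  # under sum-to-zero time coding the volume main effect is the average
  # over the four years: 0.5 + 0.05 * 1.5
  expect_equal(unname(coef(fit)["logV"]), 0.575, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["age"]), 0.01, tolerance = 1e-6)
})

test_that("REML covariance equals the sample covariance on balanced saturated data", {
  bc <- balanced_mvn_cohort(n = 40, seed = 1)
  fit <- wml_lmm(y ~ factor(visit_year), bc$df)
  expect_lt(max(abs(fit$sigma - cov(bc$Y))), 1e-6)
  expect_true(fit$converged)
  # sigma must be symmetric positive definite
  expect_lt(max(abs(fit$sigma - t(fit$sigma))), 1e-12)
  expect_gt(min(eigen(fit$sigma)$values), 0)
})

test_that("forcing a scaled-identity covariance reproduces OLS exactly", {
  bc <- balanced_mvn_cohort(n = 30, seed = 2)
  d <- bc$df
  set.seed(3); x <- rnorm(30)
  d$x <- x[d$subject_id]
  fit <- wml_lmm(y ~ x * visit_year, d, covariance = "scaled_identity")
  d$vf <- factor(d$visit_year); contrasts(d$vf) <- contr.sum(4)
  ols <- lm(y ~ x * vf, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
})

test_that("the REML optimum beats random covariance perturbations", {
  bc <- balanced_mvn_cohort(n = 25, seed = 5)
  fit <- wml_lmm(y ~ factor(visit_year), bc$df)
  d0 <- fit$dev_fun(fit$theta)
  set.seed(6)
  for (i in 1:20)
    expect_lte(d0, fit$dev_fun(fit$theta + rnorm(10, 0, 0.05)) + 1e-8)
})

test_that("estimates agree with nlme::gls on incomplete longitudinal data", {
  skip_if_not_installed("nlme")
  vols <- sample_lesion_volumes(60, seed = 11)
  cfg <- cognition_sim_config(n_subjects = 60, dropout_rate_last_visit = 0.25,
                              rng_seed = 12)
  d <- generate_cohort_cognition(vols, cfg)
  d$logV <- log(d$lesion_volume)
  fit <- wml_lmm(latent_executive ~ logV * visit_year + age_baseline, d)

  d2 <- d[is.finite(d$latent_executive), ]
  d2$vf <- factor(d2$visit_year)
  contrasts(d2$vf) <- contr.sum(4)
  g <- nlme::gls(latent_executive ~ logV * vf + age_baseline, data = d2,
                 correlation = nlme::corSymm(form = ~ as.integer(vf) | subject_id),
                 weights = nlme::varIdent(form = ~ 1 | vf), method = "REML")
  vw <- coef(g$modelStruct$varStruct, unconstrained = FALSE, allCoef = TRUE)
  sds <- g$sigma * vw[as.character(0:3)]
  Sg <- diag(sds) %*% nlme::corMatrix(g$modelStruct$corStruct)[[1]] %*% diag(sds)
  expect_lt(max(abs(fit$sigma - Sg)), 1e-3)
  expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-4)
})

test_that("effect tests expose main, interaction and per-year contrasts coherently", {
  vols <- sample_lesion_volumes(120, seed = 21)
  cfg <- cognition_sim_config(n_subjects = 120, effect_main = -0.3,
                              effect_interaction = -0.25,
                              dropout_rate_last_visit = 0.2, rng_seed = 22)
  d <- generate_cohort_cognition(vols, cfg)
  d$logV <- log(d$lesion_volume)
  fit <- wml_lmm(latent_executive ~ logV * visit_year + age_baseline + sex +
                   education, d)
  te <- test_effects(fit, "logV")
  # per-year estimates average to the main (sum-to-zero) estimate
  expect_equal(mean(te$per_year$estimate), te$main$estimate, tolerance = 1e-10)
  expect_equal(te$interaction$df1, 3)
  expect_true(all(te$per_year$df > 1))
  # strong simulated decline: later years show stronger negative effects
  expect_lt(te$per_year$estimate[4], te$per_year$estimate[1])
  expect_lt(te$interaction$p, 0.05)
  expect_error(test_effects(fit, "nonesuch"), "not found")
})

test_that("degenerate designs and tiny cohorts are refused", {
  bc <- balanced_mvn_cohort(n = 12, seed = 7)
  d <- bc$df
  d$z <- 1                                      # collinear with intercept
  expect_error(wml_lmm(y ~ z + factor(visit_year), d), "singular")
  expect_error(wml_lmm(y ~ factor(visit_year), d[d$subject_id <= 5, ]),
               ">= 10 subjects")
  d2 <- rbind(bc$df, bc$df[1, ])
  expect_error(wml_lmm(y ~ factor(visit_year), d2), "duplicate")
})

test_that("the model grid covers every predictor-outcome-adjustment cell", {
  vols <- sample_lesion_volumes(40, seed = 31)
  cfg <- cognition_sim_config(n_subjects = 40, rng_seed = 32)
  d <- generate_cohort_cognition(vols, cfg)
  norms <- fit_baseline_norms(d)
  d <- suppressMessages(compute_compound_scores(d, norms))
  set.seed(33)
  base <- data.frame(subject_id = unique(d$subject_id))
  base$V_DC33 <- 0.2 * vols * exp(rnorm(40, 0, 0.2))
  base$V_DC66 <- 0.3 * vols * exp(rnorm(40, 0, 0.2))
  base$V_DC100 <- vols * exp(rnorm(40, 0, 0.1))
  base$V_FLAIR <- vols * exp(rnorm(40, 0, 0.1))
  dd <- merge(d, base, by = "subject_id")

  grid <- run_model_grid(dd, outcomes = c("compound_executive", "mmse_total"))
  expect_equal(nrow(grid), 3 * 2 * 2)
  expect_true(all(c("main_p", "int_p", "year3_p") %in% names(grid)))
  ok <- grid$converged & is.na(grid$error)
  expect_true(all(is.finite(grid$main_F[ok])))

  # a predictor duplicating V_FLAIR must fail only in the adjusted cell
  dd$V_DC100 <- dd$V_FLAIR
  g2 <- run_model_grid(dd, predictors = "V_DC100",
                       outcomes = "compound_executive")
  expect_match(g2$error[g2$vflair_adjusted], "singular")
  expect_true(is.na(g2$error[!g2$vflair_adjusted]))
})
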