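# minimal complete battery for n subjects x visits
battery_frame <- function(n = 3, visits = 0:1, value = 10) {
  sm <- wmlstager:::compound_measures()
  subtests <- c("trail_a", "trail_b", "maze", "digit_cancellation",
                "stroop_ii", "stroop_iii", "symbol_digit", "verbal_fluency",
                "word_recall_immediate", "word_recall_delayed",
                "word_recognition", "digit_span")
  df <- expand.grid(subject_id = seq_len(n), visit_year = visits)
  for (s in subtests) df[[s]] <- value
  df
}

test_that("baseline norms are per-measure mean/SD over visit 0 only", {
  df <- battery_frame(3, visits = 0:1)
  set.seed(1)
  for (s in setdiff(names(df), c("subject_id", "visit_year")))
    df[[s]] <- df[[s]] + rnorm(nrow(df))
  df$digit_span[df$visit_year == 0] <- c(8, 10, 12)
  df$digit_span[df$visit_year == 1] <- c(100, 200, 300)   # must be ignored
  norms <- fit_baseline_norms(df)
  i <- which(norms$measure == "digit_span")
  expect_equal(norms$mean[i], 10)
  expect_equal(norms$sd[i], 2)                             # sample SD
  expect_equal(norms$sign[norms$measure == "trail_a"], -1)
  expect_equal(norms$sign[norms$measure == "stroop_diff"], -1)
  expect_equal(norms$sign[norms$measure == "digit_cancellation"], 1)

  expect_error(fit_baseline_norms(battery_frame(3)), "zero baseline SD")
  expect_error(fit_baseline_norms(battery_frame(3)[, -3]), "missing subtest")
})

test_that("a subject at the baseline mean scores zero on every compound", {
  df <- battery_frame(4, visits = 0)
  set.seed(2)
  for (s in setdiff(names(df), c("subject_id", "visit_year")))
    df[[s]] <- rnorm(4, df[[s]], 3)
  norms <- fit_baseline_norms(df)
  probe <- df[1, ]
  for (i in seq_len(nrow(norms))) {
    msr <- norms$measure[i]
    if (msr == "stroop_diff") { probe$stroop_iii <- norms$mean[i]; probe$stroop_ii <- 0 }
    else if (msr == "trail_diff") probe$trail_b <- norms$mean[i] + probe$trail_a
    else if (!msr %in% c("trail_a")) probe[[msr]] <- norms$mean[i]
  }
  probe$trail_a <- norms$mean[norms$measure == "trail_a"]
  probe$trail_b <- norms$mean[norms$measure == "trail_diff"] + probe$trail_a
  out <- compute_compound_scores(probe, norms)
  expect_equal(out$compound_speed, 0)
  expect_equal(out$compound_executive, 0)
  expect_equal(out$compound_memory, 0)
})

test_that("timed measures enter with inverted sign", {
  df <- battery_frame(3, visits = 0)
  set.seed(1)
  for (s in setdiff(names(df), c("subject_id", "visit_year")))
    df[[s]] <- df[[s]] + rnorm(nrow(df))
  df$stroop_ii <- c(40, 40, 40)
  df$stroop_iii <- c(55, 60, 65)                 # diff 15, 20, 25: mean 20 sd 5
  norms <- fit_baseline_norms(df)
  i <- which(norms$measure == "stroop_diff")
  expect_equal(norms$mean[i], 20)
  expect_equal(norms$sd[i], 5)
  probe <- df[1, ]
  probe$stroop_iii <- 60                          # diff = 20: contributes 0
  z0 <- wmlstager:::derive_difference_measures(probe)
  expect_equal(-1 * (z0$stroop_diff - 20) / 5, 0)
  probe$stroop_iii <- 70                          # diff = 30: z term = -2
  z1 <- wmlstager:::derive_difference_measures(probe)
  expect_equal(-1 * (z1$stroop_diff - 20) / 5, -2)
})

test_that("compounds equal the mean of their signed z-terms (brute force)", {
  set.seed(7)
  df <- battery_frame(20, visits = 0:3)
  for (s in setdiff(names(df), c("subject_id", "visit_year")))
    df[[s]] <- df[[s]] + rnorm(nrow(df), 0, 4)
  norms <- fit_baseline_norms(df)
  out <- compute_compound_scores(df, norms)
  d <- wmlstager:::derive_difference_measures(df)
  zval <- function(m) {
    i <- which(norms$measure == m)
    norms$sign[i] * (d[[m]] - norms$mean[i]) / norms$sd[i]
  }
  exec <- (zval("stroop_diff") + zval("trail_diff") + zval("symbol_digit") +
             zval("verbal_fluency")) / 4
  spd <- (zval("trail_a") + zval("maze") + zval("digit_cancellation")) / 3
  mem <- (zval("word_recall_immediate") + zval("word_recall_delayed") +
            zval("word_recognition") + zval("digit_span")) / 4
  expect_equal(out$compound_executive, exec)
  expect_equal(out$compound_speed, spd)
  expect_equal(out$compound_memory, mem)

  # baseline cohort mean is zero when nothing is missing
  for (cc in c("compound_speed", "compound_executive", "compound_memory"))
    expect_lt(abs(mean(out[[cc]][out$visit_year == 0])), 1e-9)
})

test_that("compounds are invariant to consistent affine rescaling of a subtest", {
  set.seed(8)
  df <- battery_frame(15, visits = 0:2)
  for (s in setdiff(names(df), c("subject_id", "visit_year")))
    df[[s]] <- df[[s]] + rnorm(nrow(df), 0, 4)
  base <- compute_compound_scores(df, fit_baseline_norms(df))
  df2 <- df
  df2$verbal_fluency <- 5 + 2.5 * df2$verbal_fluency   # same transform, all visits
  resc <- compute_compound_scores(df2, fit_baseline_norms(df2))
  expect_equal(resc$compound_executive, base$compound_executive,
               tolerance = 1e-12)
})

test_that("missing constituents propagate to a missing compound, not imputation", {
  set.seed(9)
  df <- battery_frame(10, visits = 0:1)
  for (s in setdiff(names(df), c("subject_id", "visit_year")))
    df[[s]] <- df[[s]] + rnorm(nrow(df), 0, 4)
  norms <- fit_baseline_norms(df)
  df$digit_span[11] <- NA
  out <- suppressMessages(compute_compound_scores(df, norms))
  expect_true(is.na(out$compound_memory[11]))
  expect_false(is.na(out$compound_executive[11]))
  expect_false(anyNA(out$compound_memory[-11]))
})

test_that("simulated cohorts carry the configured structure", {
  vols <- sample_lesion_volumes(200, seed = 3)
  cfg <- cognition_sim_config(n_subjects = 200,
                              dropout_rate_last_visit = 0.3, rng_seed = 5)
  df <- generate_cohort_cognition(vols, cfg)
  expect_equal(nrow(df), 800)
  n_miss <- sum(is.na(df$mmse_total[df$visit_year == 3]))
  expect_gt(n_miss, 40); expect_lt(n_miss, 80)    # binomial(200, 0.3)
  expect_identical(df, generate_cohort_cognition(vols, cfg))

  expect_error(generate_cohort_cognition(c(vols[-1], 0), cfg), "positive")
  expect_error(cognition_sim_config(residual_cov = matrix(1, 4, 4)),
               "positive definite")
  expect_error(cognition_sim_config(dropout_rate_last_visit = 1.2), "\\[0, 1\\]")
})

test_that("null effects and equal covariates give one shared trajectory", {
  cfg <- cognition_sim_config(n_subjects = 20, effect_main = 0,
                              effect_interaction = 0, beta_age = 0,
                              beta_sex = 0, beta_edu = 0,
                              residual_cov = diag(1e-18, 4),
                              subtest_noise_sd = 0,
                              dropout_rate_last_visit = 0, rng_seed = 1)
  df <- generate_cohort_cognition(rep(5, 20), cfg)
  for (v in 0:3)
    expect_lt(diff(range(df$latent_executive[df$visit_year == v])), 1e-6)
})
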