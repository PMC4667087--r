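#' Configuration of the longitudinal cognition simulator
#'
#' Defines the generative model for cohort cognition data matched to the
#' phantom lesion volumes: a latent score per cognitive domain follows a
#' linear model in log lesion volume, visit year, their interaction and
#' demographics, with multivariate-normal within-subject residuals over
#' visits (unstructured covariance); observed subtests are noisy affine
#' transforms of the latent domain, timed subtests on an inverted scale
#' (larger = slower). Demographic defaults match an elderly small-vessel
#' disease cohort (age 74.2 (4.8) years, 57.7% women, education 11.7
#' (4.3) years); last-visit dropout defaults to 28%, inside the 24-32%
#' range typical of such follow-ups.
#'
#' @param n_subjects number of subjects.
#' @param n_visits number of annual visits (must match `residual_cov`).
#' @param effect_main cross-sectional effect of log lesion volume on each
#'   latent domain (z-units per log cm^3).
#' @param effect_interaction additional change per visit-year per log
#'   cm^3 (z-units/year); negative = steeper decline with higher load.
#' @param beta0,beta_time,beta_age,beta_sex,beta_edu remaining fixed
#'   effects of the latent model (time in z/year; age and education
#'   centered at the cohort means; sex coded female = 1).
#' @param residual_cov n_visits x n_visits symmetric positive-definite
#'   within-subject residual covariance.
#' @param dropout_rate_last_visit expected fraction of subjects missing
#'   the last visit, in `[0, 1]`.
#' @param dropout_mechanism `"MCAR"` (completely at random) or `"MAR"`
#'   (probability depends on age and baseline MMSE, both observed).
#' @param age_mean,age_sd,prop_female,edu_mean,edu_sd demographics.
#' @param subtest_noise_sd measurement noise of each subtest, as a
#'   fraction of that subtest's latent slope (0 = subtests are exact
#'   affine images of the latent domain).
#' @param rng_seed integer seed.
#' @return validated `cognition_sim_config` list.
#' @export
cognition_sim_config <- function(n_subjects = 78,
                                 n_visits = 4,
                                 effect_main = -0.2,
                                 effect_interaction = -0.05,
                                 beta0 = 0,
                                 beta_time = -0.05,
                                 beta_age = -0.03,
                                 beta_sex = 0.1,
                                 beta_edu = 0.03,
                                 residual_cov = default_residual_cov(n_visits),
                                 dropout_rate_last_visit = 0.28,
                                 dropout_mechanism = c("MCAR", "MAR"),
                                 age_mean = 74.2, age_sd = 4.8,
                                 prop_female = 0.577,
                                 edu_mean = 11.7, edu_sd = 4.3,
                                 subtest_noise_sd = 0.3,
                                 rng_seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_visits = as.integer(n_visits),
              effect_main = effect_main, effect_interaction = effect_interaction,
              beta0 = beta0, beta_time = beta_time, beta_age = beta_age,
              beta_sex = beta_sex, beta_edu = beta_edu,
              residual_cov = residual_cov,
              dropout_rate_last_visit = dropout_rate_last_visit,
              dropout_mechanism = match.arg(dropout_mechanism),
              age_mean = age_mean, age_sd = age_sd, prop_female = prop_female,
              edu_mean = edu_mean, edu_sd = edu_sd,
              subtest_noise_sd = subtest_noise_sd,
              rng_seed = as.integer(rng_seed))
  if (cfg$dropout_rate_last_visit < 0 || cfg$dropout_rate_last_visit > 1)
    stopf("dropout_rate_last_visit must be in [0, 1]")
  rc <- cfg$residual_cov
  if (!is.matrix(rc) || nrow(rc) != cfg$n_visits || ncol(rc) != cfg$n_visits)
    stopf("residual_cov must be %d x %d", cfg$n_visits, cfg$n_visits)
  if (max(abs(rc - t(rc))) > 1e-8) stopf("residual_cov must be symmetric")
  ok <- tryCatch({ chol(rc); TRUE }, error = function(e) FALSE)
  if (!ok) stopf("residual_cov must be positive definite")
  structure(cfg, class = "cognition_sim_config")
}

#' Default within-subject residual covariance
#'
#' Mildly increasing variances and decaying-but-not-AR correlations, so
#' the unstructured-covariance machinery is genuinely exercised.
#'
#' @param n_visits number of visits.
#' @return n_visits x n_visits covariance matrix.
#' @export
default_residual_cov <- function(n_visits = 4) {
  sds <- seq(1, 1.15, length.out = n_visits)
  corr <- diag(n_visits)
  lagcor <- c(0.70, 0.55, 0.45, 0.35, 0.30)
  for (i in seq_len(n_visits)) for (j in seq_len(n_visits))
    if (i != j) corr[i, j] <- lagcor[abs(i - j)]
  diag(sds) %*% corr %*% diag(sds)
}

#' Sample baseline lesion volumes for a simulated cohort
#'
#' Log-normal volumes on the scale of visible white-matter lesion loads
#' in an elderly small-vessel disease cohort (median ~15 cm^3, long
#' right tail).
#'
#' @param n number of subjects.
#' @param meanlog,sdlog log-normal parameters (log cm^3).
#' @param seed integer seed.
#' @return numeric vector of volumes (cm^3).
#' @export
sample_lesion_volumes <- function(n, meanlog = 2.7, sdlog = 1.0, seed = 1L) {
  with_seed(seed, exp(rnorm(n, meanlog, sdlog)))
}

# subtest measurement model: intercept, slope on the domain latent, domain.
# Negative slopes are the timed subtests (seconds; larger = slower).
subtest_model <- function() {
  data.frame(
    subtest = c("trail_a", "maze", "digit_cancellation",
                "stroop_ii", "stroop_iii", "trail_b",
                "symbol_digit", "verbal_fluency",
                "word_recall_immediate", "word_recall_delayed",
                "word_recognition", "digit_span"),
    domain = c("speed", "speed", "speed",
               "executive", "executive", "executive",
               "executive", "executive",
               "memory", "memory", "memory", "memory"),
    intercept = c(45, 30, 50, 25, 50, 110, 40, 20, 20, 7, 20, 6),
    slope = c(-12, -8, 10, -3, -10, -25, 8, 5, 4, 2.5, 3, 1.5),
    stringsAsFactors = FALSE)
}

#' Simulate a longitudinal cohort cognition table
#'
#' One row per subject-visit. Latent domain scores (speed, executive,
#' memory, global) follow the configured linear model in log baseline
#' lesion volume, visit year and demographics with multivariate-normal
#' within-subject residuals; observed subtests, MMSE and VADAS are noisy
#' transforms of the latents (VADAS and timed subtests inverted: higher =
#' worse/slower). Last-visit scores are deleted at the configured dropout
#' rate; demographics are retained for dropped visits. Latent columns
#' (`latent_*`) are included as simulation ground truth.
#'
#' @param volumes positive baseline lesion volume (cm^3) per subject.
#' @param config a [cognition_sim_config()].
#' @return data.frame with subject_id, visit_year, demographics, subtest
#'   scores, mmse_total, vadas_total, lesion_volume and latent truth.
#' @export
generate_cohort_cognition <- function(volumes, config = cognition_sim_config()) {
  stopifnot(inherits(config, "cognition_sim_config"))
  n <- config$n_subjects
  if (length(volumes) != n)
    stopf("need one baseline lesion volume per subject (%d != %d)",
          length(volumes), n)
  if (any(!is.finite(volumes) | volumes <= 0))
    stopf("lesion volumes must be positive (log transform undefined); apply the epsilon floor upstream")
  m <- config$n_visits
  logv <- log(volumes)

  with_seed(config$rng_seed, {
    age <- rnorm(n, config$age_mean, config$age_sd)
    sex <- ifelse(runif(n) < config$prop_female, "F", "M")
    edu <- pmax(round(rnorm(n, config$edu_mean, config$edu_sd)), 0)
    Lc <- chol(config$residual_cov)
    years <- seq_len(m) - 1

    domains <- c("speed", "executive", "memory", "global")
    lat <- array(NA_real_, c(n, m, length(domains)),
                 dimnames = list(NULL, NULL, domains))
    for (d in seq_along(domains)) {
      mu <- outer(config$beta0 + config$effect_main * logv +
                    config$beta_age * (age - config$age_mean) +
                    config$beta_sex * (sex == "F") +
                    config$beta_edu * (edu - config$edu_mean),
                  rep(1, m)) +
            outer(rep(1, n), config$beta_time * years) +
            outer(config$effect_interaction * logv, years)
      eps <- matrix(rnorm(n * m), n, m) %*% Lc
      lat[, , d] <- mu + eps
    }

    sm <- subtest_model()
    df <- data.frame(subject_id = rep(sprintf("S%03d", seq_len(n)), each = m),
                     visit_year = rep(years, n),
                     age_baseline = rep(age, each = m),
                     sex = rep(sex, each = m),
                     education = rep(edu, each = m),
                     lesion_volume = rep(volumes, each = m),
                     stringsAsFactors = FALSE)
    for (k in seq_len(nrow(sm))) {
      latvals <- t(lat[, , sm$domain[k]])          # m x n -> row order matches df
      noise_sd <- config$subtest_noise_sd * abs(sm$slope[k])
      df[[sm$subtest[k]]] <- sm$intercept[k] + sm$slope[k] * as.vector(latvals) +
        rnorm(n * m, 0, noise_sd)
    }
    glat <- as.vector(t(lat[, , "global"]))
    df$mmse_total <- pmin(pmax(27 + 2 * glat +
                                 rnorm(n * m, 0, config$subtest_noise_sd * 2), 0), 30)
    df$vadas_total <- pmax(15 - 4 * glat +
                             rnorm(n * m, 0, config$subtest_noise_sd * 4), 0)
    for (d in domains)
      df[[paste0("latent_", d)]] <- as.vector(t(lat[, , d]))

    # last-visit dropout
    if (config$dropout_rate_last_visit > 0 && m > 1) {
      if (config$dropout_mechanism == "MCAR") {
        p <- rep(config$dropout_rate_last_visit, n)
      } else {
        zage <- (age - mean(age)) / sd(age)
        mmse0 <- df$mmse_total[df$visit_year == 0]
        zmm <- (mmse0 - mean(mmse0)) / sd(mmse0)
        lp <- 0.7 * zage - 0.5 * zmm
        p <- plogis(qlogis(config$dropout_rate_last_visit) + lp - mean(lp))
      }
      drop <- runif(n) < p
      score_cols <- c(sm$subtest, "mmse_total", "vadas_total",
                      paste0("latent_", domains))
      sel <- df$visit_year == max(years) & rep(drop, each = m)
      df[sel, score_cols] <- NA
    }
    df
  })
}
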