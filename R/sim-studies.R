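#' Monte-Carlo study of the volume-by-time interaction test
#'
#' Repeatedly simulates cohorts from the cognition generator at a given
#' interaction effect, fits the REML model on the latent executive score
#' (the outcome that follows the generative model exactly) and records
#' the interaction test and the recovered per-year linear slope of the
#' volume effect. With `effect_interaction = 0` the rejection rate
#' estimates the type-I error of the interaction test; otherwise it
#' estimates power, and the mean slope estimates the interaction
#' effect itself (z-units per year per log cm^3).
#'
#' @param n_reps number of simulated cohorts.
#' @param n_subjects subjects per cohort.
#' @param effect_interaction true interaction effect (z/yr per log cm^3).
#' @param effect_main true main effect at baseline.
#' @param dropout_rate_last_visit,dropout_mechanism last-visit dropout.
#' @param outcome outcome column fitted (default `latent_executive`).
#' @param alpha nominal level of the interaction test.
#' @param seed master seed; replicate r uses a seed derived from it.
#' @return list: `results` data.frame (one row per replicate:
#'   `p_interaction`, `reject`, `slope_hat`, `converged`),
#'   `rejection_rate`, `mean_slope`, `mc_se_slope`, settings.
#' @export
interaction_sim_study <- function(n_reps, n_subjects = 100,
                                  effect_interaction = 0,
                                  effect_main = -0.2,
                                  dropout_rate_last_visit = 0.3,
                                  dropout_mechanism = "MCAR",
                                  outcome = "latent_executive",
                                  alpha = 0.05, seed = 1L) {
  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    s <- derive_seed(seed, r)
    vols <- sample_lesion_volumes(n_subjects, seed = derive_seed(s, 1))
    cfg <- cognition_sim_config(n_subjects = n_subjects,
                                effect_main = effect_main,
                                effect_interaction = effect_interaction,
                                dropout_rate_last_visit = dropout_rate_last_visit,
                                dropout_mechanism = dropout_mechanism,
                                rng_seed = derive_seed(s, 2))
    df <- generate_cohort_cognition(vols, cfg)
    df$logV <- log(df$lesion_volume)
    row <- tryCatch({
      fml <- stats::as.formula(
        paste(outcome, "~ logV * visit_year + age_baseline + sex + education"))
      fit <- wml_lmm(fml, df)
      te <- test_effects(fit, "logV")
      yrs <- as.numeric(te$per_year$year)
      w <- (yrs - mean(yrs)) / sum((yrs - mean(yrs))^2)   # linear slope contrast
      data.frame(p_interaction = te$interaction$p,
                 reject = te$interaction$p < alpha,
                 slope_hat = sum(w * te$per_year$estimate),
                 main_hat = te$main$estimate,
                 converged = fit$converged)
    }, error = function(e)
      data.frame(p_interaction = NA, reject = NA, slope_hat = NA,
                 main_hat = NA, converged = FALSE))
    res[[r]] <- row
  }
  results <- do.call(rbind, res)
  ok <- results$converged & is.finite(results$slope_hat)
  list(results = results,
       rejection_rate = mean(results$reject[ok]),
       mean_slope = mean(results$slope_hat[ok]),
       mc_se_slope = sd(results$slope_hat[ok]) / sqrt(sum(ok)),
       n_converged = sum(ok),
       effect_interaction = effect_interaction, n_subjects = n_subjects,
       n_reps = n_reps, alpha = alpha)
}

#' Replicated progression-enrichment study on growth phantoms
#'
#' For each replicate, generates a longitudinal growth phantom, segments
#' baseline and final visit independently, and measures how often
#' baseline DC33 voxels (small partial lesion content) lie inside the
#' follow-up hard lesion mask relative to the chance rate in baseline
#' normal-appearing white matter.
#'
#' @param n_reps number of phantom replicates.
#' @param grid_shape,voxel_size_mm phantom grid; the defaults are the
#'   standard phantom geometry (other settings are the
#'   [phantom_config()] defaults). Coarser grids thin the DC33 rim band
#'   to a handful of voxels and make the per-replicate fractions
#'   unstable.
#' @param K,lambda segmentation settings.
#' @param seed master seed; replicate r derives its own.
#' @return data.frame, one row per replicate: `n_dc33`, `fraction`,
#'   `chance_rate`, `enrichment`.
#' @export
progression_enrichment_study <- function(n_reps = 20,
                                         grid_shape = c(96, 96, 24),
                                         voxel_size_mm = c(2, 2, 6),
                                         K = 6, lambda = 10, seed = 1L) {
  rows <- lapply(seq_len(n_reps), function(r) {
    s <- derive_seed(seed, 500 + r)
    cfg <- phantom_config(grid_shape = grid_shape,
                          voxel_size_mm = voxel_size_mm, rng_seed = s)
    ph <- suppressWarnings(generate_longitudinal_phantom(cfg))
    seg_visit <- function(v) {
      feats <- normalize_channels(ph$visits[[v]])
      seeds <- generate_seed_labels(feats, seed = derive_seed(s, v))
      model <- suppressMessages(dc_fit(feats, seeds, K = K, lambda = lambda,
                                       seed = derive_seed(s, 10 + v)))
      list(tpm = tissue_probabilities(model, feats))
    }
    b <- seg_visit(1); f <- seg_visit(cfg$n_visits)
    cb <- categorize_voxels(b$tpm); cf <- categorize_voxels(f$tpm)
    pr <- suppressWarnings(progression_overlap(cb, cf, b$tpm))
    data.frame(n_dc33 = pr$n_dc33_baseline,
               fraction = pr$fraction_dc33_to_lesion,
               chance_rate = pr$chance_rate, enrichment = pr$enrichment)
  })
  do.call(rbind, rows)
}
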