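#' @name pipeline
#' @title End-to-end reproducible pipeline
#'
#' @description `run_pipeline()` chains simulate -> segment/stage ->
#' score -> analyze on a synthetic cohort: per-subject longitudinal
#' phantoms are written as NIfTI, segmented per visit into tissue
#' probabilities and lesion stages, compared against ground truth and
#' the conventional FLAIR surrogate, matched with simulated cognition
#' scored into compound measures, and analyzed with the REML model grid.
#' Every stage derives its seed from the master seed by a fixed offset,
#' all outputs are hashed into a run manifest, and completed stages are
#' skipped on resume.
NULL

#' Default pipeline configuration
#'
#' A desk-scale demonstration cohort: 12 subjects on a 48 x 48 x 16 grid
#' of 4 x 4 x 7.5 mm voxels over 4 annual visits, with between-subject
#' variation in lesion focus count and core radius so baseline lesion
#' volumes spread over an order of magnitude.
#'
#' @return nested configuration list (YAML-serializable).
#' @export
default_pipeline_config <- function() {
  list(
    cohort = list(n_subjects = 12),
    phantom = list(grid_shape = c(48, 48, 16), voxel_size_mm = c(4, 4, 7.5),
                   noise_sigma = 5, bias_field_amplitude = 0.05,
                   n_visits = 4, focus_core_radius_mm = 6, rim_width_mm = 4,
                   growth_rate_mm_per_year = 1.5,
                   n_lesion_foci_range = c(2, 8),
                   core_radius_jitter_sd = 0.2),
    segmentation = list(K = 6, lambda = 10, confidence_fraction = 0.1,
                        max_iter = 100, tol = 1e-4),
    conventional = list(k_sd = 2.5, min_component_voxels = 4),
    cognition = list(effect_main = -0.2, effect_interaction = -0.05,
                     dropout_rate_last_visit = 0.28,
                     dropout_mechanism = "MCAR"),
    analysis = list(predictors = c("V_DC33", "V_DC66", "V_DC100"),
                    outcomes = c("mmse_total", "vadas_total", "compound_speed",
                                 "compound_executive", "compound_memory"),
                    adjust_vflair = c(FALSE, TRUE)))
}

pipeline_channels <- c("FLAIR", "T2", "MT")

#' Run the full pipeline
#'
#' @param config configuration list (see [default_pipeline_config()]) or
#'   path to a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @param master_seed integer; per-stage and per-subject seeds are
#'   derived from it by fixed offsets.
#' @param force re-run stages whose outputs already exist.
#' @return the run manifest (invisibly written to
#'   `out_dir/manifest.json`): config snapshot, seeds, package version,
#'   per-stage output hashes and wall-clock seconds.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         master_seed = 1L, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))

  stages <- list()
  stage <- function(name, outputs, fun) {
    t0 <- Sys.time()
    paths <- file.path(out_dir, outputs)
    if (!force && length(paths) > 0 && all(file.exists(paths))) {
      message(sprintf("[%s] outputs present; skipped (use force = TRUE to re-run)", name))
      ran <- FALSE
    } else {
      tryCatch(fun(), error = function(e)
        stopf("pipeline stage '%s' failed: %s (inputs preserved in %s)",
              name, conditionMessage(e), out_dir))
      ran <- TRUE
    }
    stages[[name]] <<- list(
      ran = ran,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      files = hash_files(out_dir, outputs))
    invisible(NULL)
  }

  n_sub <- config$cohort$n_subjects
  subj_ids <- sprintf("S%03d", seq_len(n_sub))
  img_dir <- file.path(out_dir, "images"); seg_dir <- file.path(out_dir, "segmentation")
  dir.create(img_dir, showWarnings = FALSE); dir.create(seg_dir, showWarnings = FALSE)
  pc <- config$phantom
  n_visits <- pc$n_visits

  # ---- stage 1: simulate ---------------------------------------------------
  stage("simulate", c("truth.csv"), function() {
    truth_rows <- list()
    for (s in seq_len(n_sub)) {
      sseed <- derive_seed(master_seed, 100 + s)
      draw <- with_seed(sseed, list(
        n_foci = sample(pc$n_lesion_foci_range[1]:pc$n_lesion_foci_range[2], 1),
        radius = pc$focus_core_radius_mm * exp(rnorm(1, 0, pc$core_radius_jitter_sd))))
      pcfg <- phantom_config(
        grid_shape = pc$grid_shape, voxel_size_mm = pc$voxel_size_mm,
        noise_sigma = pc$noise_sigma,
        bias_field_amplitude = pc$bias_field_amplitude,
        n_lesion_foci = draw$n_foci, focus_core_radius_mm = draw$radius,
        rim_width_mm = pc$rim_width_mm,
        growth_rate_mm_per_year = pc$growth_rate_mm_per_year,
        n_visits = n_visits, rng_seed = derive_seed(sseed, 7))
      ph <- generate_longitudinal_phantom(pcfg)
      write_channel(ph$truth$brain_mask, file.path(img_dir, sprintf("%s_mask.nii", subj_ids[s])),
                    voxel_size_mm = pcfg$voxel_size_mm, datatype = "uint8")
      for (v in seq_len(n_visits)) {
        for (ch in ph$visits[[v]]$channels)
          write_channel(ch, file.path(img_dir, sprintf("%s_v%d_%s.nii", subj_ids[s],
                                                       v - 1, ch$channel_name)))
        write_channel(ph$truth$fraction_maps[[v]]$LESION,
                      file.path(img_dir, sprintf("%s_v%d_lesionfrac.nii", subj_ids[s], v - 1)),
                      voxel_size_mm = pcfg$voxel_size_mm)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          subject_id = subj_ids[s], visit_year = v - 1,
          true_volume = ph$truth$true_volumes[v], n_foci = draw$n_foci)
      }
    }
    write.csv(do.call(rbind, truth_rows), file.path(out_dir, "truth.csv"),
              row.names = FALSE)
  })

  # ---- stage 2: segment + stage + volumes ----------------------------------
  stage("segment", c("volumes.csv"), function() {
    vol_rows <- list(); rep_rows <- list()
    for (s in seq_len(n_sub)) {
      mask <- read_channel(file.path(img_dir, sprintf("%s_mask.nii", subj_ids[s])), "mask")
      mask_arr <- mask$data > 0.5
      cats <- vector("list", n_visits); tpms <- vector("list", n_visits)
      for (v in seq_len(n_visits)) {
        chans <- lapply(pipeline_channels, function(nm)
          read_channel(file.path(img_dir, sprintf("%s_v%d_%s.nii", subj_ids[s], v - 1, nm)), nm))
        msv <- assemble_multispectral(chans, mask_arr)
        feats <- normalize_channels(msv)
        sg <- config$segmentation
        seeds <- generate_seed_labels(feats, sg$confidence_fraction,
                                      seed = derive_seed(master_seed, 200 + s * 10 + v))
        model <- dc_fit(feats, seeds, K = sg$K, lambda = sg$lambda,
                        max_iter = sg$max_iter, tol = sg$tol,
                        seed = derive_seed(master_seed, 300 + s * 10 + v))
        tpm <- tissue_probabilities(model, feats)
        cat_map <- categorize_voxels(tpm)
        flair_seg <- segment_flair_conventional(
          chans[[1]], mask_arr, k_sd = config$conventional$k_sd,
          min_component_voxels = config$conventional$min_component_voxels)
        vs <- compute_volumes(cat_map, flair_seg)
        write_channel(category_array(cat_map),
                      file.path(seg_dir, sprintf("%s_v%d_categories.nii", subj_ids[s], v - 1)),
                      voxel_size_mm = mask$voxel_size_mm, datatype = "uint8")
        write_channel(tissue_prob_array(tpm, "LESION"),
                      file.path(seg_dir, sprintf("%s_v%d_plesion.nii", subj_ids[s], v - 1)),
                      voxel_size_mm = mask$voxel_size_mm)
        truth_frac <- read_channel(
          file.path(img_dir, sprintf("%s_v%d_lesionfrac.nii", subj_ids[s], v - 1)), "truth")$data
        vol_rows[[length(vol_rows) + 1]] <- cbind(
          data.frame(subject_id = subj_ids[s], visit_year = v - 1),
          as.data.frame(vs),
          data.frame(dice_dc_truth = dice_coefficient(dchard_mask(cat_map),
                                                      truth_frac > 0.5)))
        cats[[v]] <- cat_map; tpms[[v]] <- tpm
        if (v == 1) {
          pv <- partial_volume_recovery(truth_frac, tpm)
          rep_rows[[length(rep_rows) + 1]] <- data.frame(
            subject_id = subj_ids[s], pv_pearson_r = pv$pearson_r, n_rim = pv$n_rim)
        }
      }
      pr <- suppressWarnings(progression_overlap(cats[[1]], cats[[n_visits]], tpms[[1]]))
      rep_rows[[length(rep_rows)]]$progression_fraction <- pr$fraction_dc33_to_lesion
      rep_rows[[length(rep_rows)]]$progression_chance <- pr$chance_rate
      rep_rows[[length(rep_rows)]]$progression_enrichment <- pr$enrichment
    }
    write.csv(do.call(rbind, vol_rows), file.path(out_dir, "volumes.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, rep_rows), file.path(out_dir, "phantom_report.csv"),
              row.names = FALSE)
  })

  # ---- stage 3: score ------------------------------------------------------
  stage("score", c("cognition.csv"), function() {
    truth <- read.csv(file.path(out_dir, "truth.csv"))
    base_vol <- truth$true_volume[truth$visit_year == 0][order(truth$subject_id[truth$visit_year == 0])]
    cg <- config$cognition
    ccfg <- cognition_sim_config(
      n_subjects = n_sub, n_visits = n_visits,
      effect_main = cg$effect_main, effect_interaction = cg$effect_interaction,
      dropout_rate_last_visit = cg$dropout_rate_last_visit,
      dropout_mechanism = cg$dropout_mechanism,
      rng_seed = derive_seed(master_seed, 400))
    cog <- generate_cohort_cognition(pmax(base_vol, 1e-3), ccfg)
    norms <- fit_baseline_norms(cog)
    cog <- suppressMessages(compute_compound_scores(cog, norms))
    write.csv(cog, file.path(out_dir, "cognition.csv"), row.names = FALSE)
  })

  # ---- stage 4: analyze ----------------------------------------------------
  stage("analyze", c("results.csv"), function() {
    vols <- read.csv(file.path(out_dir, "volumes.csv"))
    cog <- read.csv(file.path(out_dir, "cognition.csv"))
    base <- vols[vols$visit_year == 0,
                 c("subject_id", "V_DC33", "V_DC66", "V_DC100", "V_FLAIR")]
    merged <- merge(cog, base, by = "subject_id")
    an <- config$analysis
    eps <- prod(pc$voxel_size_mm) / 1000
    grid <- run_model_grid(merged, predictors = an$predictors,
                           outcomes = an$outcomes,
                           adjust_vflair = an$adjust_vflair,
                           epsilon_log = eps)
    write.csv(grid, file.path(out_dir, "results.csv"), row.names = FALSE)
  })

  manifest <- list(
    package_version = as.character(packageVersion("wmlstager")),
    master_seed = master_seed,
    config = config,
    stages = stages,
    hashes = hash_files(out_dir, setdiff(list.files(out_dir, recursive = TRUE),
                                         "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# md5 of files under dir, keyed by relative path
hash_files <- function(dir, rel_paths) {
  rel_paths <- rel_paths[file.exists(file.path(dir, rel_paths))]
  h <- tools::md5sum(file.path(dir, rel_paths))
  setNames(as.character(h), rel_paths)
}

#' Content hashes of a pipeline run
#'
#' Extracts the output-file hash table of a manifest (sorted by path),
#' the quantity two runs of the same configuration and master seed must
#' agree on exactly.
#'
#' @param manifest a [run_pipeline()] manifest (or path to
#'   `manifest.json`).
#' @return named character vector of md5 hashes.
#' @export
manifest_hashes <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  h <- unlist(manifest$hashes)
  h[order(names(h))]
}
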