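#' Default tissue intensity signatures
#'
#' Mean noiseless intensity (arbitrary units) of each tissue on each
#' channel. The orderings encode the contrast the staging rules rely on:
#' on the FLAIR-like channel LESION > GM >= WM > CSF (CSF suppressed,
#' lesions hyperintense); on the T2-like channel CSF is brightest; on the
#' MT/T1-like channel WM is brightest and CSF darkest.
#'
#' @return 4x3 numeric matrix, rows CSF/GM/WM/LESION, columns
#'   FLAIR/T2/MT.
#' @export
default_tissue_signatures <- function() {
  sig <- rbind(CSF    = c(25, 180,  30),
               GM     = c(110, 110, 100),
               WM     = c(95,  90, 130),
               LESION = c(160, 150,  70))
  colnames(sig) <- c("FLAIR", "T2", "MT")
  sig
}

#' Configuration of the synthetic multispectral phantom
#'
#' Defines the geometry, intensity model and lesion-growth model of the
#' longitudinal phantom. Defaults emulate the study conditions this
#' package targets: three channels, four tissue classes, strongly
#' anisotropic voxels (thick axial slices), four annual visits, and
#' lesion foci whose partial-volume rim at baseline turns into fully
#' developed lesion at follow-up.
#'
#' @param grid_shape integer(3) grid size in voxels.
#' @param voxel_size_mm numeric(3) voxel size in mm.
#' @param tissue_signatures 4 x n_channels matrix of mean intensities
#'   (rows CSF, GM, WM, LESION).
#' @param noise_sigma Gaussian noise SD (intensity units).
#' @param bias_field_amplitude smooth multiplicative bias amplitude `a`;
#'   the field lies in `[1 - a, 1 + a]`.
#' @param n_lesion_foci number of lesion foci.
#' @param focus_core_radius_mm baseline core radius (fraction 1 inside).
#' @param rim_width_mm width of the linear partial-volume ramp.
#' @param growth_rate_mm_per_year added core radius per visit-year.
#' @param n_visits number of annual visits (baseline + follow-ups).
#' @param periventricular_bias weight >= 0 biasing focus sampling toward
#'   the ventricles (0 = uniform in white matter).
#' @param rng_seed integer seed governing foci placement and noise.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(96, 96, 24),
                           voxel_size_mm = c(2, 2, 6),
                           tissue_signatures = default_tissue_signatures(),
                           noise_sigma = 5,
                           bias_field_amplitude = 0.05,
                           n_lesion_foci = 8,
                           focus_core_radius_mm = 6,
                           rim_width_mm = 4,
                           growth_rate_mm_per_year = 1.5,
                           n_visits = 4,
                           periventricular_bias = 0,
                           rng_seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              tissue_signatures = tissue_signatures,
              noise_sigma = noise_sigma,
              bias_field_amplitude = bias_field_amplitude,
              n_lesion_foci = as.integer(n_lesion_foci),
              focus_core_radius_mm = focus_core_radius_mm,
              rim_width_mm = rim_width_mm,
              growth_rate_mm_per_year = growth_rate_mm_per_year,
              n_visits = as.integer(n_visits),
              periventricular_bias = periventricular_bias,
              rng_seed = as.integer(rng_seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3, all(cfg$grid_shape > 0),
            length(cfg$voxel_size_mm) == 3, all(cfg$voxel_size_mm > 0),
            cfg$noise_sigma >= 0,
            cfg$bias_field_amplitude >= 0, cfg$bias_field_amplitude <= 1,
            cfg$n_lesion_foci >= 0, cfg$focus_core_radius_mm > 0,
            cfg$rim_width_mm > 0, cfg$growth_rate_mm_per_year >= 0,
            cfg$n_visits >= 1)
  sig <- cfg$tissue_signatures
  if (!all(TISSUES %in% rownames(sig)))
    stopf("tissue_signatures must have rows %s", paste(TISSUES, collapse = ", "))
  if (any(!is.finite(sig))) stopf("tissue_signatures must be finite")
  fl <- sig[, 1]
  if (!(fl["LESION"] > fl["GM"] && fl["GM"] >= fl["WM"] && fl["WM"] > fl["CSF"]))
    stopf("FLAIR-like channel must order LESION > GM >= WM > CSF; got %s",
          paste(sprintf("%s=%g", TISSUES, fl[TISSUES]), collapse = ", "))
  invisible(cfg)
}

# Ellipsoidal brain anatomy: GM outer shell, WM interior, two ellipsoidal
# ventricles (CSF). Returns hard base fractions plus masks and voxel-center
# coordinates (mm).
phantom_anatomy <- function(cfg) {
  dm <- cfg$grid_shape
  cc <- voxel_centers_mm(dm, cfg$voxel_size_mm)
  fov <- dm * cfg$voxel_size_mm
  ctr <- (dm - 1) * cfg$voxel_size_mm / 2
  semi <- c(0.42, 0.45, 0.40) * fov

  X <- array(cc$x, dm)
  Y <- array(rep(cc$y, each = dm[1]), dm)
  Z <- array(rep(cc$z, each = dm[1] * dm[2]), dm)
  r2 <- function(center, s)
    ((X - center[1]) / s[1])^2 + ((Y - center[2]) / s[2])^2 +
    ((Z - center[3]) / s[3])^2

  brain <- r2(ctr, semi) <= 1
  gm_shell <- brain & r2(ctr, 0.88 * semi) > 1
  vsemi <- c(0.12, 0.40, 0.22) * semi
  vent <- (r2(ctr + c(-0.18 * semi[1], 0, 0), vsemi) <= 1) |
          (r2(ctr + c(+0.18 * semi[1], 0, 0), vsemi) <= 1)
  vent <- vent & brain & !gm_shell
  wm <- brain & !gm_shell & !vent

  base <- list(CSF = array(0, dm), GM = array(0, dm),
               WM = array(0, dm), LESION = array(0, dm))
  base$CSF[vent] <- 1; base$GM[gm_shell] <- 1; base$WM[wm] <- 1
  list(brain_mask = brain, wm_mask = wm, vent_mask = vent,
       base_fractions = base, coords = list(X = X, Y = Y, Z = Z),
       center = ctr)
}

#' Lesion fraction field from focus centers
#'
#' Each focus contributes fraction 1 inside its core radius, a linear ramp
#' down to 0 across the rim width, and 0 beyond; overlapping foci combine
#' by maximum. White matter damage is modelled as a gradual process, so
#' partial-volume voxels form a graded rim around every focus.
#'
#' @param mask 3-D logical array the field is restricted to (fraction 0
#'   outside); every focus center must lie inside it.
#' @param foci numeric matrix n x 3 of focus centers in mm (voxel-center
#'   coordinates, 0-based grid).
#' @param core_radius core radius in mm; scalar or one per focus.
#' @param rim_width rim (ramp) width in mm, > 0.
#' @param voxel_size_mm numeric(3).
#' @return 3-D array of lesion fractions in `[0, 1]`.
#' @export
generate_lesion_fraction_field <- function(mask, foci, core_radius, rim_width,
                                           voxel_size_mm) {
  stopifnot(length(dim(mask)) == 3, rim_width > 0)
  dm <- dim(mask)
  foci <- matrix(foci, ncol = 3)
  core_radius <- rep_len(core_radius, nrow(foci))
  cc <- voxel_centers_mm(dm, voxel_size_mm)
  frac <- array(0, dm)
  for (i in seq_len(nrow(foci))) {
    f <- foci[i, ]
    vox <- round(f / voxel_size_mm) + 1
    if (any(vox < 1) || any(vox > dm) || !mask[vox[1], vox[2], vox[3]])
      stopf("lesion focus %d at (%.1f, %.1f, %.1f) mm lies outside the mask",
            i, f[1], f[2], f[3])
    d <- sqrt(outer(outer((cc$x - f[1])^2, (cc$y - f[2])^2, `+`),
                    (cc$z - f[3])^2, `+`))
    fi <- pmin(pmax(1 - (d - core_radius[i]) / rim_width, 0), 1)
    frac <- pmax(frac, fi)
  }
  frac[!mask] <- 0
  frac
}

#' Mix tissue fractions into noisy multispectral intensities
#'
#' Forward intensity model: the noiseless intensity of channel k at voxel
#' v is `sum_t fraction_t(v) * signature(t, k)`, multiplied by a smooth
#' multiplicative bias field in `[1 - a, 1 + a]` (shared across channels),
#' plus zero-mean Gaussian noise. This is what creates the
#' partial-volume voxels the segmenter must recover.
#'
#' @param fraction_maps named list (CSF, GM, WM, LESION) of 3-D fraction
#'   arrays summing to 1 per voxel.
#' @param signatures tissue x channel intensity matrix.
#' @param noise_sigma Gaussian noise SD.
#' @param bias_amplitude bias field amplitude in `[0, 1]`.
#' @param seed integer RNG seed (same seed, same volume).
#' @param brain_mask 3-D logical array copied into the output.
#' @param voxel_size_mm numeric(3).
#' @return A `multispectral_volume`.
#' @export
mix_intensities <- function(fraction_maps, signatures, noise_sigma,
                            bias_amplitude, seed, brain_mask, voxel_size_mm) {
  if (!all(TISSUES %in% names(fraction_maps)))
    stopf("fraction_maps must be named %s", paste(TISSUES, collapse = ", "))
  if (!all(TISSUES %in% rownames(signatures)))
    stopf("missing signature row(s): %s",
          paste(setdiff(TISSUES, rownames(signatures)), collapse = ", "))
  dm <- dim(fraction_maps[[1]])
  tot <- Reduce(`+`, fraction_maps[TISSUES])
  if (max(abs(tot[brain_mask] - 1)) > 1e-6)
    stopf("tissue fractions do not sum to 1 inside the mask")
  channels <- colnames(signatures) %||% paste0("ch", seq_len(ncol(signatures)))
  with_seed(seed, {
    bias <- smooth_bias_field(dm, voxel_size_mm, bias_amplitude)
    chans <- lapply(seq_along(channels), function(k) {
      img <- array(0, dm)
      for (t in TISSUES) img <- img + fraction_maps[[t]] * signatures[t, k]
      img <- img * bias
      if (noise_sigma > 0) img <- img + array(rnorm(prod(dm), 0, noise_sigma), dm)
      new_channel_image(img, voxel_size_mm, affine = NULL,
                        channel_name = channels[k])
    })
    assemble_multispectral(chans, brain_mask)
  })
}

# Smooth multiplicative bias: product of low-frequency cosines with random
# phase/frequency, rescaled into [1 - a, 1 + a]. Consumes RNG draws.
smooth_bias_field <- function(dm, voxel_size_mm, amplitude) {
  if (amplitude == 0) { runif(6); return(array(1, dm)) }
  fov <- dm * voxel_size_mm
  cc <- voxel_centers_mm(dm, voxel_size_mm)
  fr <- runif(3, 0.3, 0.9); ph <- runif(3, 0, 2 * pi)
  f <- outer(outer(cos(2 * pi * fr[1] * cc$x / fov[1] + ph[1]),
                   cos(2 * pi * fr[2] * cc$y / fov[2] + ph[2]), `*`),
             cos(2 * pi * fr[3] * cc$z / fov[3] + ph[3]), `*`)
  1 + amplitude * array(f, dm)
}

#' Generate a longitudinal multispectral phantom with known truth
#'
#' Places lesion foci in white matter and grows each core radius by
#' `growth_rate_mm_per_year` per visit, so baseline rim voxels (partial
#' lesion) become fully developed lesion at later visits — the growth
#' pattern in which small partial lesion volumes mark future locations of
#' full lesions. Returns per-visit volumes plus the complete ground truth.
#'
#' @param config a [phantom_config()].
#' @param max_retries focus re-sampling attempts before giving up when a
#'   lesion would outgrow the white matter.
#' @return list with `visits` (list of `multispectral_volume`) and
#'   `truth` (class `phantom_truth`: `fraction_maps` per visit,
#'   `lesion_foci`, `true_volumes` in cm^3, `nawm_mask`, masks, config).
#' @export
generate_longitudinal_phantom <- function(config, max_retries = 50L) {
  validate_phantom_config(config)
  anat <- phantom_anatomy(config)
  dm <- config$grid_shape
  vox_cm3 <- prod(config$voxel_size_mm) / 1000
  last_extent <- config$focus_core_radius_mm + config$rim_width_mm +
    config$growth_rate_mm_per_year * (config$n_visits - 1)

  foci <- with_seed(config$rng_seed,
                    sample_wm_foci(anat, config, last_extent, max_retries))

  fractions <- vector("list", config$n_visits)
  true_vol <- numeric(config$n_visits)
  for (v in seq_len(config$n_visits)) {
    r_v <- config$focus_core_radius_mm +
      config$growth_rate_mm_per_year * (v - 1)
    lf <- if (nrow(foci) > 0)
      generate_lesion_fraction_field(anat$wm_mask, foci, r_v,
                                     config$rim_width_mm, config$voxel_size_mm)
    else array(0, dm)
    fr <- anat$base_fractions
    fr$LESION <- lf
    fr$WM <- fr$WM * (1 - lf)
    fractions[[v]] <- fr
    true_vol[v] <- sum(lf) * vox_cm3
  }

  visits <- lapply(seq_len(config$n_visits), function(v)
    mix_intensities(fractions[[v]], config$tissue_signatures,
                    config$noise_sigma, config$bias_field_amplitude,
                    seed = derive_seed(config$rng_seed, v),
                    brain_mask = anat$brain_mask,
                    voxel_size_mm = config$voxel_size_mm))

  truth <- structure(list(
    fraction_maps = fractions,
    lesion_foci = list(centers_mm = foci,
                       core_radius_mm = config$focus_core_radius_mm +
                         config$growth_rate_mm_per_year *
                         (seq_len(config$n_visits) - 1)),
    true_volumes = true_vol,
    nawm_mask = fractions[[1]]$WM >= 0.99,
    brain_mask = anat$brain_mask, wm_mask = anat$wm_mask,
    config = config), class = "phantom_truth")
  list(visits = visits, truth = truth)
}

# Sample focus centers uniformly (or periventricularly biased) in white
# matter such that the final-visit lesion extent stays inside WM.
sample_wm_foci <- function(anat, cfg, last_extent, max_retries) {
  if (cfg$n_lesion_foci == 0)
    return(matrix(numeric(0), 0, 3))
  wm_idx <- which(anat$wm_mask)
  co <- arrayInd(wm_idx, cfg$grid_shape)
  mm <- sweep(co - 1, 2, cfg$voxel_size_mm, `*`)
  wt <- rep(1, length(wm_idx))
  if (cfg$periventricular_bias > 0) {
    vidx <- which(anat$vent_mask)
    if (length(vidx) > 0) {
      vmm <- sweep(arrayInd(vidx, cfg$grid_shape) - 1, 2, cfg$voxel_size_mm, `*`)
      # distance to nearest ventricle voxel, subsampled for speed
      sub <- vmm[seq(1, nrow(vmm), length.out = min(200, nrow(vmm))), , drop = FALSE]
      dmin <- apply(mm, 1, function(p) sqrt(min(colSums((t(sub) - p)^2))))
      wt <- exp(-cfg$periventricular_bias * dmin / 10)
    }
  }
  foci <- matrix(NA_real_, cfg$n_lesion_foci, 3)
  for (i in seq_len(cfg$n_lesion_foci)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      j <- sample.int(length(wm_idx), 1, prob = wt)
      cand <- mm[j, ]
      if (ball_inside_wm(cand, last_extent, anat, cfg)) {
        foci[i, ] <- cand; ok <- TRUE; break
      }
      if (try == 1L)
        warnf("lesion focus %d would outgrow the white matter; re-sampling", i)
    }
    if (!ok)
      stopf("could not place lesion focus %d inside white matter after %d tries (extent %.1f mm)",
            i, max_retries, last_extent)
  }
  foci
}

ball_inside_wm <- function(center, radius, anat, cfg) {
  dm <- cfg$grid_shape
  lo <- pmax(floor((center - radius) / cfg$voxel_size_mm) + 1, 1)
  hi <- pmin(ceiling((center + radius) / cfg$voxel_size_mm) + 1, dm)
  xs <- (lo[1]:hi[1] - 1) * cfg$voxel_size_mm[1]
  ys <- (lo[2]:hi[2] - 1) * cfg$voxel_size_mm[2]
  zs <- (lo[3]:hi[3] - 1) * cfg$voxel_size_mm[3]
  d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, `+`),
              (zs - center[3])^2, `+`)
  sub <- anat$wm_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  all(sub[d2 <= radius^2])
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Phantom truth: %d visits, %d lesion foci, true volumes (cm^3): %s\n",
              length(x$fraction_maps), nrow(x$lesion_foci$centers_mm),
              paste(sprintf("%.2f", x$true_volumes), collapse = ", ")))
  invisible(x)
}
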