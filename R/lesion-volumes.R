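#' @name lesion-volumes
#' @title Partial-volume lesion staging and derived volumes
#'
#' @description Tissue probabilities are converted into a three-stage
#' lesion classification per voxel: DC100 (lesion is the most probable
#' tissue with probability > 2/3), DC66 (lesion most probable but <= 2/3)
#' and DC33 (lesion only the second most probable tissue, with
#' probability >= 1/3). DC100 and DC66 voxels contain a majority of
#' lesion tissue, so their combined volume V_DCHARD is the estimate of
#' visible lesion load; DC33 voxels are never counted as lesion by
#' conventional segmentation and represent possible early-stage damage.
NULL

LESION_CATEGORIES <- c("NONE", "DC33", "DC66", "DC100")

#' Stage in-mask voxels into lesion categories
#'
#' @param tpm a `tissue_prob_map`.
#' @param t_high threshold separating DC100 from DC66 (default 2/3,
#'   reading the printed 66% as two thirds; probability exactly at the
#'   threshold goes to DC66).
#' @param t_small minimum lesion probability for DC33 (default 1/3,
#'   inclusive).
#' @return a `lesion_category_map`: factor `category` per in-mask voxel,
#'   `voxel_idx`, grid `dim`, `voxel_size_mm`, `thresholds`.
#' @export
categorize_voxels <- function(tpm, t_high = 2 / 3, t_small = 1 / 3) {
  stopifnot(inherits(tpm, "tissue_prob_map"))
  p <- tpm$prob
  if (max(abs(rowSums(p) - 1)) > 1e-6)
    stopf("tissue probability vectors do not sum to 1")
  li <- match("LESION", colnames(p))
  top <- max.col(p, ties.method = "first")
  p2 <- p; p2[cbind(seq_len(nrow(p)), top)] <- -Inf
  second <- max.col(p2, ties.method = "first")
  pl <- p[, li]
  cat <- rep("NONE", nrow(p))
  cat[top == li & pl > t_high] <- "DC100"
  cat[top == li & pl <= t_high] <- "DC66"
  cat[top != li & second == li & pl >= t_small] <- "DC33"
  structure(list(category = factor(cat, levels = LESION_CATEGORIES),
                 voxel_idx = tpm$voxel_idx, dim = tpm$dim,
                 voxel_size_mm = tpm$voxel_size_mm,
                 thresholds = c(t_high = t_high, t_small = t_small)),
            class = "lesion_category_map")
}

#' Full-grid integer array of lesion categories
#'
#' Codes: 0 NONE/background, 1 DC33, 2 DC66, 3 DC100.
#'
#' @param cat a `lesion_category_map`.
#' @return 3-D integer array.
#' @export
category_array <- function(cat) {
  stopifnot(inherits(cat, "lesion_category_map"))
  a <- array(0L, cat$dim)
  a[cat$voxel_idx] <- as.integer(cat$category) - 1L
  a
}

# logical array of the DC hard lesion mask (DC66 union DC100)
dchard_mask <- function(cat) category_array(cat) >= 2L

#' Dice similarity coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty masks agree perfectly on
#' absence and score 1; one empty and one not score 0.
#'
#' @param maskA,maskB logical arrays on the same grid.
#' @return Dice score in `[0, 1]`.
#' @export
dice_coefficient <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) stopf("mask grids do not match")
  a <- sum(maskA); b <- sum(maskB)
  if (a + b == 0) return(1)
  2 * sum(maskA & maskB) / (a + b)
}

#' Derived lesion volumes from a category map
#'
#' Each volume is the voxel count times the voxel volume, reported in
#' cm^3. `V_DCHARD = V_DC66 + V_DC100` by construction. When a
#' conventional FLAIR lesion mask is supplied, the Dice score between it
#' and the DC hard mask is included.
#'
#' @param cat a `lesion_category_map`.
#' @param flair_mask optional logical array (conventional segmentation).
#' @return a `volume_summary`: volumes `V_DC33`, `V_DC66`, `V_DC100`,
#'   `V_DCHARD`, `V_FLAIR` (cm^3), `dice_flair_dchard`, `voxel_counts`.
#' @export
compute_volumes <- function(cat, flair_mask = NULL) {
  stopifnot(inherits(cat, "lesion_category_map"))
  vox_cm3 <- prod(cat$voxel_size_mm) / 1000
  counts <- table(cat$category)
  v <- as.numeric(counts[c("DC33", "DC66", "DC100")]) * vox_cm3
  hard <- dchard_mask(cat)
  v_flair <- NA_real_; dce <- NA_real_
  if (!is.null(flair_mask)) {
    if (!identical(dim(flair_mask), cat$dim))
      stopf("FLAIR mask grid does not match the category map grid")
    v_flair <- sum(flair_mask) * vox_cm3
    dce <- dice_coefficient(flair_mask, hard)
  }
  structure(list(V_DC33 = v[1], V_DC66 = v[2], V_DC100 = v[3],
                 V_DCHARD = v[2] + v[3], V_FLAIR = v_flair,
                 dice_flair_dchard = dce,
                 voxel_counts = counts, voxel_cm3 = vox_cm3),
            class = "volume_summary")
}

#' @export
print.volume_summary <- function(x, ...) {
  cat(sprintf("Partial WML volumes (cm^3): V_DC33 = %.2f, V_DC66 = %.2f, V_DC100 = %.2f, V_DCHARD = %.2f\n",
              x$V_DC33, x$V_DC66, x$V_DC100, x$V_DCHARD))
  if (!is.na(x$V_FLAIR))
    cat(sprintf("Conventional V_FLAIR = %.2f cm^3, Dice(V_FLAIR, V_DCHARD) = %.3f\n",
                x$V_FLAIR, x$dice_flair_dchard))
  invisible(x)
}

#' @export
as.data.frame.volume_summary <- function(x, ...) {
  data.frame(V_DC33 = x$V_DC33, V_DC66 = x$V_DC66, V_DC100 = x$V_DC100,
             V_DCHARD = x$V_DCHARD, V_FLAIR = x$V_FLAIR,
             dice_flair_dchard = x$dice_flair_dchard)
}

#' Conventional FLAIR lesion segmentation surrogate
#'
#' Stand-in for semi-automated slice-wise local thresholding: on each
#' axial slice, hyperintense voxels above `mean + k_sd * SD` of the
#' in-mask slice intensities (mean and SD computed excluding the top 1%
#' to keep the lesions themselves from inflating the threshold) are kept,
#' then 26-connected components smaller than `min_component_voxels` are
#' removed.
#'
#' @param flair a `channel_image` (FLAIR-like).
#' @param mask 3-D logical brain mask.
#' @param k_sd threshold multiplier, > 0. The default 2.5 makes the
#'   surrogate's boundary track the visible-lesion level set (about 50%
#'   lesion content) on phantoms with the default tissue contrasts.
#' @param min_component_voxels minimum component size kept (default 4).
#' @return 3-D logical lesion mask.
#' @export
segment_flair_conventional <- function(flair, mask, k_sd = 2.5,
                                       min_component_voxels = 4L) {
  stopifnot(inherits(flair, "channel_image"))
  if (k_sd <= 0) stopf("k_sd must be > 0")
  if (!identical(dim(flair$data), dim(mask))) stopf("mask grid mismatch")
  out <- array(FALSE, dim(mask))
  for (z in seq_len(dim(mask)[3])) {
    m <- mask[, , z]
    if (sum(m) < 50) {
      if (sum(m) > 0)
        warnf("slice %d has only %d in-mask voxels; skipped", z, sum(m))
      next
    }
    vals <- flair$data[, , z][m]
    core <- vals[vals <= stats::quantile(vals, 0.99, names = FALSE)]
    s <- sd(core)
    if (!is.finite(s) || s == 0) next
    thr <- mean(core) + k_sd * s
    out[, , z] <- m & flair$data[, , z] > thr
  }
  prune_small_components(out, min_component_voxels)
}

#' Overlap of baseline small-lesion voxels with follow-up lesions
#'
#' Tests whether voxels staged DC33 at baseline (small partial lesion
#' content, invisible to conventional segmentation) preferentially become
#' fully developed lesion (DC66 or DC100) at follow-up, compared with the
#' chance rate among baseline normal-appearing white matter.
#'
#' @param baseline,followup `lesion_category_map`s on the same grid,
#'   follow-up chronologically after baseline.
#' @param baseline_tpm the baseline `tissue_prob_map` (defines NAWM:
#'   category NONE with WM the most probable tissue).
#' @return a `progression_result`: `n_dc33_baseline`,
#'   `fraction_dc33_to_lesion`, `chance_rate`, `enrichment`.
#' @export
progression_overlap <- function(baseline, followup, baseline_tpm) {
  stopifnot(inherits(baseline, "lesion_category_map"),
            inherits(followup, "lesion_category_map"),
            inherits(baseline_tpm, "tissue_prob_map"))
  if (!identical(baseline$dim, followup$dim) ||
      !identical(baseline$voxel_idx, followup$voxel_idx))
    stopf("baseline and follow-up category maps are not on the same grid/mask")
  if (!identical(baseline$voxel_idx, baseline_tpm$voxel_idx))
    stopf("baseline probability map does not match the category map")

  fu_hard <- followup$category %in% c("DC66", "DC100")
  b33 <- baseline$category == "DC33"
  n33 <- sum(b33)
  frac <- if (n33 == 0) {
    warnf("no DC33 voxels at baseline; progression fraction undefined")
    NaN
  } else mean(fu_hard[b33])

  wm_top <- max.col(baseline_tpm$prob, ties.method = "first") ==
    match("WM", colnames(baseline_tpm$prob))
  nawm <- baseline$category == "NONE" & wm_top
  chance <- if (sum(nawm) == 0) NaN else mean(fu_hard[nawm])
  enrich <- if (is.nan(frac) || is.nan(chance)) NaN
            else if (chance == 0) { if (frac > 0) Inf else NaN }
            else frac / chance
  structure(list(n_dc33_baseline = n33,
                 fraction_dc33_to_lesion = frac,
                 chance_rate = chance, enrichment = enrich,
                 n_nawm = sum(nawm)),
            class = "progression_result")
}

#' @export
print.progression_result <- function(x, ...) {
  cat(sprintf("Progression: %d baseline DC33 voxels, %.1f%% inside follow-up DCHARD (NAWM chance rate %.2f%%, enrichment %.1fx)\n",
              x$n_dc33_baseline, 100 * x$fraction_dc33_to_lesion,
              100 * x$chance_rate, x$enrichment))
  invisible(x)
}

#' Partial-volume recovery diagnostics on a phantom
#'
#' Bins rim voxels (true lesion fraction strictly between 0 and 1) by
#' true fraction and reports the mean estimated lesion probability per
#' bin plus the Pearson correlation between true fraction and estimated
#' P(LESION) over all rim voxels.
#'
#' @param true_fraction 3-D array of true lesion fractions.
#' @param tpm a `tissue_prob_map` on the same grid.
#' @param bins bin centers (default 0.2, 0.4, 0.6, 0.8, half-width 0.1).
#' @return list with `bin_means` (named numeric), `pearson_r`, `n_rim`.
#' @export
partial_volume_recovery <- function(true_fraction, tpm,
                                    bins = c(0.2, 0.4, 0.6, 0.8)) {
  stopifnot(inherits(tpm, "tissue_prob_map"),
            identical(dim(true_fraction), tpm$dim))
  tf <- true_fraction[tpm$voxel_idx]
  pl <- tpm$prob[, "LESION"]
  rim <- tf > 0 & tf < 1
  bw <- if (length(bins) > 1) diff(bins)[1] / 2 else 0.1
  bm <- vapply(bins, function(b) mean(pl[rim & abs(tf - b) <= bw]), numeric(1))
  names(bm) <- sprintf("%.1f", bins)
  list(bin_means = bm,
       pearson_r = if (sum(rim) > 2) cor(tf[rim], pl[rim]) else NA_real_,
       n_rim = sum(rim))
}
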