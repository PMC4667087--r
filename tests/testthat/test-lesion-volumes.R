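test_that("voxels are staged by the 2/3 and 1/3 probability rules", {
  p <- rbind(c(.05, .05, .10, .80),    # lesion dominant, > 2/3  -> DC100
             c(.05, .10, .35, .50),    # lesion dominant, <= 2/3 -> DC66
             c(.05, .10, .50, .35),    # lesion second, >= 1/3   -> DC33
             c(.10, .20, .50, .20),    # below every rule        -> NONE
             c(1/12, 1/12, 1/6, 2/3),  # exactly 2/3             -> DC66
             c(.05, .10, 31/60, 1/3))  # exactly 1/3, second     -> DC33
  cm <- categorize_voxels(make_tpm(p))
  expect_equal(as.character(cm$category),
               c("DC100", "DC66", "DC33", "NONE", "DC66", "DC33"))
  expect_false(anyNA(cm$category))     # partition is exhaustive

  bad <- make_tpm(rbind(c(.3, .3, .3, .3)))
  expect_error(categorize_voxels(bad), "sum to 1")
})

test_that("volumes are voxel counts times voxel volume, with exact additivity", {
  cm <- make_catmap(rep(c("DC100", "DC66", "DC33", "NONE"),
                        c(100, 40, 30, 50)), voxel_size_mm = c(2, 2, 6))
  vs <- compute_volumes(cm)
  expect_equal(vs$V_DC100, 2.4)        # 100 voxels of 24 mm^3
  expect_equal(vs$V_DC66, 0.96)
  expect_equal(vs$V_DC33, 0.72)
  expect_identical(vs$V_DCHARD, vs$V_DC66 + vs$V_DC100)

  empty <- make_catmap(rep("NONE", 10))
  vs0 <- compute_volumes(empty, flair_mask = array(FALSE, c(10, 1, 1)))
  expect_equal(vs0$V_DCHARD, 0)
  expect_equal(vs0$dice_flair_dchard, 1)          # agreement on absence
})

test_that("additivity and category exclusivity hold on segmented phantoms", {
  seg <- small_segmentation()
  cm <- categorize_voxels(seg$tpm)
  vs <- compute_volumes(cm)
  expect_identical(vs$V_DCHARD, vs$V_DC66 + vs$V_DC100)
  arr <- category_array(cm)
  expect_equal(sum(arr == 1 & arr >= 2), 0)       # DC33 disjoint from DCHARD
  expect_equal(sum(table(cm$category)), length(cm$voxel_idx))
})

test_that("Dice matches its definition and conventions", {
  a <- array(FALSE, c(4, 4, 1)); b <- a
  a[1:3] <- TRUE; b[2:4] <- TRUE                  # |A|=3, |B|=3, overlap 2
  expect_equal(dice_coefficient(a, b), 2 * 2 / 6)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a), 0)
  expect_equal(dice_coefficient(a & FALSE, b), 0) # mixed empty/nonempty
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  expect_error(dice_coefficient(a, array(TRUE, c(2, 2, 2))), "grids")
})

test_that("conventional FLAIR thresholding finds the hyperintense core", {
  ph0 <- noiseless_phantom()
  flair <- ph0$visits[[1]]$channels[[1]]
  mask <- ph0$truth$brain_mask
  seg <- suppressWarnings(segment_flair_conventional(flair, mask))
  tf <- ph0$truth$fraction_maps[[1]]$LESION
  # the surrogate's boundary must be a level set of the true fraction:
  # everything it keeps is lesion-bearing, everything clearly above the
  # operator threshold is kept
  expect_gte(min(tf[seg]), 0.15)
  expect_true(all(seg[tf >= 0.95]))
  expect_equal(sum(seg & tf == 0), 0)

  unif <- flair; unif$data[] <- 100
  expect_equal(sum(suppressWarnings(segment_flair_conventional(unif, mask))), 0)
  expect_error(segment_flair_conventional(flair, mask, k_sd = 0), "k_sd")
})

test_that("progression overlap separates rim conversion from chance", {
  base <- make_catmap(c("DC33", "DC33", "DC33", "DC33", "NONE", "NONE",
                        "NONE", "DC66"))
  fu   <- make_catmap(c("DC66", "DC100", "DC66", "NONE", "NONE", "DC66",
                        "NONE", "DC100"))
  wmish <- rbind(c(.1, .1, .6, .2))[rep(1, 8), ]
  tpm <- make_tpm(wmish)
  pr <- progression_overlap(base, fu, tpm)
  expect_equal(pr$n_dc33_baseline, 4)
  expect_equal(pr$fraction_dc33_to_lesion, 0.75)
  expect_equal(pr$chance_rate, 1 / 3)             # one of three NAWM voxels
  expect_equal(pr$enrichment, 0.75 / (1 / 3))

  # identical maps: no DC33 voxel can already be DCHARD (categories exclusive)
  pr0 <- progression_overlap(base, base, tpm)
  expect_equal(pr0$fraction_dc33_to_lesion, 0)

  none <- make_catmap(rep("NONE", 8))
  expect_warning(prN <- progression_overlap(none, fu, tpm), "no DC33")
  expect_true(is.nan(prN$fraction_dc33_to_lesion))
})

test_that("complete rim conversion yields fraction one on growth phantoms", {
  ph <- small_phantom()
  feats0 <- normalize_channels(ph$visits[[1]])
  # categories straight from the ground-truth fractions: estimator-free check
  truth_tpm <- function(v) {
    fr <- ph$truth$fraction_maps[[v]]
    idx <- feats0$voxel_idx
    p <- cbind(CSF = fr$CSF[idx], GM = fr$GM[idx],
               WM = fr$WM[idx], LESION = fr$LESION[idx])
    structure(list(prob = p / rowSums(p), voxel_idx = idx, dim = dim(fr$CSF),
                   voxel_size_mm = ph$truth$config$voxel_size_mm),
              class = "tissue_prob_map")
  }
  base <- categorize_voxels(truth_tpm(1))
  fu <- categorize_voxels(truth_tpm(4))
  pr <- progression_overlap(base, fu, truth_tpm(1))
  # growth (4.5 mm over 3 years) exceeds the DC33 band depth of the rim
  expect_equal(pr$fraction_dc33_to_lesion, 1)
  expect_gt(pr$enrichment, 1)
})
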