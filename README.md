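# wmlstager

Staging of white-matter lesions (WML) from multispectral brain MRI, and
REML mixed models linking the staged lesion volumes to longitudinal
cognitive decline.

WML are the core imaging marker of cerebral small vessel disease. A
voxel on thick-slice FLAIR is called "lesion" or "not lesion", but the
underlying damage is gradual: at lesion rims, voxels hold intermediate
fractions of lesion tissue long before they become frank
hyperintensities. `wmlstager` is for researchers who want to quantify
those early, partial-volume stages and test whether they carry
independent prognostic information about cognition.

The pipeline:

1. **Segmentation** — self-supervised discriminative clustering of the
   3-channel intensity vectors (FLAIR, T2, MT/T1-like). Clusters
   minimize
   `J = Σ_v ‖x_v − μ_c(v)‖² + λ Σ_{v∈seeds} (1 − P(label_v | c(v)))`,
   where the seed labels are generated from the data itself by mapping a
   coarse clustering to tissues via canonical intensity-rank signatures.
   Gaussian-kernel responsibilities then give each voxel a probability
   vector over CSF/GM/WM/LESION.
2. **Staging** — per voxel: `DC100` if lesion is the top tissue with
   p > 2/3, `DC66` if top but ≤ 2/3, `DC33` if lesion is only the
   *second* most probable tissue with p ≥ 1/3. Volumes `V_DC33`,
   `V_DC66`, `V_DC100` in cm³, with `V_DCHARD = V_DC66 + V_DC100` the
   visible-lesion estimate, compared by Dice against a conventional
   slice-wise FLAIR thresholding surrogate (`V_FLAIR`).
3. **Cognition** — compound domain scores from baseline-standardized
   subtest z-scores: speed = (Trail A + maze + digit cancellation)/3,
   executive = ((Stroop III−II) + (Trail B−A) + symbol digit + verbal
   fluency)/4, memory = (immediate + delayed recall + recognition +
   digit span)/4, timed measures sign-flipped.
4. **Longitudinal models** — `y_i ~ N(X_i β, Σ[o_i, o_i])` per subject
   over four annual visits, Σ unstructured 4×4 estimated by REML over
   its log-Cholesky factor, time as a sum-to-zero categorical factor,
   volumes entering as `log(V + ε)`; Wald F tests with Satterthwaite
   degrees of freedom for the volume main effect, the volume × time
   interaction, and per-year contrasts.

Because the clinical data this design targets is not public, the package
includes a first-class synthetic module: longitudinal multispectral
phantoms with exact tissue-fraction ground truth and growing lesions,
plus a matched cognition simulator — so everything above is testable
end to end against known truth.

## Worked example

```r
library(wmlstager)

cfg <- phantom_config(grid_shape = c(64, 64, 20),
                      voxel_size_mm = c(3, 3, 6), rng_seed = 7)
ph <- generate_longitudinal_phantom(cfg)
print(ph$truth)
#> Phantom truth: 4 visits, 8 lesion foci, true volumes (cm^3): 19.03, 30.51, 45.91, 66.23

msv   <- ph$visits[[1]]                      # baseline visit
feats <- normalize_channels(msv)
seeds <- generate_seed_labels(feats, seed = 1)
model <- dc_fit(feats, seeds, seed = 1)
print(model)
#> Discriminative clustering model: K = 6, lambda = 10, tau = 3.269
#>   converged: TRUE after 83 iterations; objective 1.776e+04 -> 1.602e+04

tpm    <- tissue_probabilities(model, feats)
stages <- categorize_voxels(tpm)
conv   <- segment_flair_conventional(msv$channels[[1]], msv$brain_mask)
compute_volumes(stages, conv)
#> Partial WML volumes (cm^3): V_DC33 = 0.38, V_DC66 = 11.07, V_DC100 = 5.18, V_DCHARD = 16.25
#> Conventional V_FLAIR = 15.28 cm^3, Dice(V_FLAIR, V_DCHARD) = 0.887

pv <- partial_volume_recovery(ph$truth$fraction_maps[[1]]$LESION, tpm)
round(pv$bin_means, 3)
#>   0.2   0.4   0.6   0.8
#> 0.161 0.213 0.389 0.535
```

Reading the output: the baseline phantom truly contains 19.0 cm³ of
lesion tissue (integrated fraction). The stager finds 16.3 cm³ of
visible lesion (`V_DCHARD`), close to the conventional surrogate's
15.3 cm³ with Dice 0.89 between the two masks, plus 0.38 cm³ of
small-stage `DC33` voxels that conventional segmentation does not count
at all. The estimated lesion probability rises monotonically with the
true lesion fraction across rim voxels (r = 0.97) — the partial-volume
signal the staging is built on.

For a full cohort run (simulate → segment → stage → score → analyze,
with a hashed manifest):

```r
man <- run_pipeline(default_pipeline_config(), "out/demo", master_seed = 1)
read.csv("out/demo/results.csv")   # model grid shaped like a results table
```

or from the shell: `inst/scripts/wml-stager run --out out/demo --seed 1`.

## Package layout

- `R/phantom.R`, `R/phantom-cognition.R` — synthetic data generators
  (ground truth included).
- `R/imaging-io.R` — NIfTI I/O and the co-registration contract.
- `R/dc-segment.R` — normalization, self-supervised seeds, `dc_fit()`,
  tissue probabilities.
- `R/lesion-volumes.R` — staging, volumes, Dice, conventional surrogate,
  progression overlap.
- `R/cognition.R` — baseline norms and compound scores.
- `R/reml.R` — `wml_lmm()`, `test_effects()`, `run_model_grid()`.
- `R/pipeline.R` — `run_pipeline()` with manifest and resume.
- `vignettes/wml-staging-methods.Rmd` — the model, its assumptions,
  parameter choices and limitations.
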