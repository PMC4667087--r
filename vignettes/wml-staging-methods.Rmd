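---
title: "Staging white-matter lesions and modelling their cognitive consequences: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging white-matter lesions and modelling their cognitive consequences: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

White-matter lesions (WML) are the main imaging marker of cerebral small
vessel disease. On conventional FLAIR images a lesion is either "visible"
or it is not; yet the disease is a gradual process, and a voxel may hold
20% or 40% lesion tissue long before it becomes a frank hyperintensity.
With thick axial slices (5-7.5 mm against 1 mm in-plane), such
partial-volume voxels are abundant at lesion rims. This package implements
a pipeline that (i) segments co-registered multispectral MRI (FLAIR-, T2-
and MT/T1-like channels) into *probabilistic* tissue memberships with a
self-supervised discriminative clustering method, (ii) stages every voxel
by its lesion content into small (DC33), intermediate (DC66) and fully
developed (DC100) categories, and (iii) relates the staged volumes to
longitudinal cognitive decline with REML linear mixed models using an
unstructured within-subject covariance over four annual visits.

Because no suitable clinical dataset is publicly deposited, the package
ships a synthetic phantom and cognition generator with exact ground
truth, and every claim the test suite makes is evaluated against that
truth.

## Discriminative clustering segmentation

Each in-mask voxel is a point $x_v \in \mathbb{R}^3$ of
robustly normalized channel intensities (per channel: subtract the
in-mask median, divide by $1.4826\,\mathrm{MAD}$; if the MAD collapses on
piecewise-constant data the SD is used). The model minimizes

$$J = \sum_v \lVert x_v - \mu_{c(v)}\rVert^2
      \;+\; \lambda \sum_{v \in \mathcal{S}} \bigl(1 - P(\ell_v \mid c(v))\bigr),$$

by alternating assignment and update steps, where $\mathcal{S}$ is a
small self-generated seed set with tissue labels $\ell_v$ and
$P(t \mid c)$ is the Laplace-smoothed ($\alpha = 1$) label distribution
of cluster $c$. With $\lambda = 0$ the procedure is exactly Lloyd
K-means, which the tests exploit as an independent oracle. Ties in
assignment go to the lowest cluster index; an emptied cluster is
re-seeded from the farthest voxel. Discriminative clustering appears in the
segmentation literature at varying levels of detail; this package fixes
one concrete, fully documented instantiation with the properties the
approach is valued for: near-uniform clusters, label-consistent
partitions, and per-voxel tissue probabilities.

**Self-supervised seeds.** A coarse 4-group clustering is mapped to
tissues by matching each group's channel-wise intensity rank signature
(e.g. on FLAIR: lesion brightest, CSF darkest; on T2: CSF brightest; on
MT: WM brightest) against the canonical signature table over all 24
permutations; an ambiguous match is an error, not a guess. The
initialization of those 4 groups is deterministic and contrast-anchored:
each group starts from the componentwise median of the voxels scoring
highest on its tissue's centered rank contrast, with prevalence-aware
top fractions (0.2% for lesion, 1% for CSF, 10% for GM/WM). This matters
because lesions can be well under 1% of brain voxels, and a
variance-driven random start then never allocates them a group — the
failure mode is silent and catastrophic (the GM upper tail gets labeled
lesion). Within each mapped group, only the `confidence_fraction`
(default 10%, at most 25%) of voxels nearest the group center become
seeds; on default-noise phantoms their purity against ground truth
exceeds 99%.

**Soft memberships.** Cluster responsibilities are Gaussian,
$P(c \mid x) \propto \exp(-\lVert x-\mu_c\rVert^2 / 2\tau^2)$, and
tissue probabilities are $P(t \mid x) = \sum_c P(t \mid c) P(c \mid x)$.
The temperature $\tau$ is set to the RMS distance between voxels and
their *second-nearest* centroid. This is a deliberate design choice: the
more obvious within-cluster RMS makes $P(\mathrm{LESION} \mid x)$ a
near-step function of the true lesion fraction (transition width about
0.05), which empties the intermediate stages and defeats partial-volume
estimation, whereas the second-nearest scale measures the local
inter-cluster separation and yields graded memberships across tissue
boundaries. On the default phantom the correlation between true lesion
fraction and estimated lesion probability over rim voxels is about 0.95.

**Defaults.** $K = 6$ and $\lambda = 10$. $K = 6$ keeps one to two
clusters per tissue so that every cluster stays anchored by seed labels;
with many more clusters the rim voxels fall into seedless clusters whose
smoothed label prior is uniform, flattening the probabilities. $\lambda$
on the order of 10 dominates the $O(1)$ squared distances of normalized
features without freezing the geometry. Both remain user-settable, and
raising $K$ is sensible for strongly multimodal real data.

## Lesion staging and volumes

Given the probability vector $p$ of a voxel: DC100 if lesion is the most
probable tissue with $p_{\mathrm{LES}} > 2/3$; DC66 if lesion is most
probable but $p_{\mathrm{LES}} \le 2/3$; DC33 if lesion is the *second*
most probable tissue with $p_{\mathrm{LES}} \ge 1/3$; otherwise NONE.
The 66%/33% thresholds are read as exact thirds, the boundary value
$2/3$ goes to DC66, and the thresholds are stored in the result so
alternative readings (0.66/0.33) are a configuration change, not a code
change. Volumes are voxel counts times voxel volume in cm³, with
$V_{\mathrm{DCHARD}} = V_{\mathrm{DC66}} + V_{\mathrm{DC100}}$ exact by
construction — the estimate of conventionally visible lesion load. The
Dice coefficient defines agreement between binary masks; two empty masks
score 1 (perfect agreement on absence), one empty against one not
scores 0.

The conventional-segmentation surrogate mimics slice-wise operator
thresholding: per axial slice, voxels above mean $+ k\,\mathrm{SD}$ of
the in-mask intensities (moments computed after discarding the top 1%,
so the lesions themselves do not inflate the threshold), followed by
removal of 26-connected components under 4 voxels. $k = 2.5$ was chosen
so that on noiseless phantoms the surrogate's boundary tracks the
visible-lesion level set (about 50% lesion content); it is a surrogate
for a human operator, stated as such, not a reproduction of one.

The progression analysis asks whether baseline DC33 voxels — invisible
to conventional segmentation — preferentially lie inside the follow-up
hard lesion mask, against the chance rate among baseline
normal-appearing white matter (category NONE, WM most probable). The
enrichment ratio of those two rates exceeds 1 in essentially all growth
phantoms.

## The synthetic phantom

Geometry is deliberately minimal: an ellipsoidal brain with a GM shell,
WM interior and two ellipsoidal ventricles — the simplest layout with
all four tissues and a periventricular WM zone. Lesion foci are sampled
in WM (uniformly by default; a periventricular bias weight is available
because where early partial-volume voxels arise relative to existing
lesions is genuinely open — the generator supports both rim-adjacent
and detached foci without asserting which dominates). Each focus
contributes lesion fraction 1 inside its core radius and a linear ramp
over a 4 mm rim; growth adds 1.5 mm/year to the core, so baseline rim
voxels (fractions 0.3-0.6) become full lesion by the third follow-up —
the pattern in which small partial volumes mark future lesion sites.
Intensities mix linearly over the four tissue fractions, times a smooth
multiplicative bias field (amplitude 0.05), plus Gaussian noise
(SD 5 against tissue contrasts of 15-65 units, i.e. realistic 1.5 T
SNR). Rician noise is deliberately not used: segmentation operates far
from the low-SNR magnitude regime where the distinction matters.

The default grid is 96 × 96 × 24 voxels of 2 × 2 × 6 mm — slice
anisotropy comparable to thick-slice clinical protocols at desk-scale
cost. What the phantom does **not** emulate: anatomical variability,
infarcts and lacunes (hyperintensity around them is disregarded in the
clinical protocol being emulated and does not exist here), motion and
ghosting, multi-center intensity drift beyond the smooth bias field, and
MR physics (TE/TR/TI are metadata only). Passing tests therefore
demonstrate correctness of the algorithms under the stated forward
model, not clinical performance.

## Simulated cognition

One latent trajectory per domain (speed, executive, memory, global)
follows

$$y_{ij} = \beta_0 + \beta_v \log V_i + \beta_t t_j
  + \beta_{vt} \log V_i\, t_j + \beta_a \mathrm{age}_i
  + \beta_s \mathrm{sex}_i + \beta_e \mathrm{edu}_i + \varepsilon_{ij},$$

with $\varepsilon_i \sim N(0, \Sigma)$ across the four visits, $\Sigma$
symmetric positive definite with mildly increasing variances and
non-AR correlations (0.70/0.55/0.45 by lag) so the unstructured
machinery is genuinely exercised. Demographics match an elderly SVD
cohort: age 74.2 (4.8), 57.7% women, education 11.7 (4.3) years; the
default cohort size is 78. Observed subtests are noisy affine images of
their domain latent; timed subtests (Trail Making, Stroop, maze) are
emitted on inverted scales (larger = slower) so the scoring module's
sign handling is genuinely exercised; VADAS is likewise
higher-is-worse. Last-visit scores are deleted at 28% by default
(within the 24-32% attrition range typical of such follow-ups), either
completely at random or, optionally, MAR with the probability depending
on age and baseline MMSE — both observed, so likelihood-based fits
remain consistent. The `latent_*` columns are retained as ground truth;
statistical calibration checks fit them directly so that the fitted
model is exactly the generating model.

## Compound cognitive scores

Speed = (Trail A + maze + digit cancellation)/3, executive =
((Stroop III−II) + (Trail B−A) + symbol digit + verbal fluency)/4,
memory = (immediate recall + delayed recall + recognition + digit
span)/4, each term a z-score against the **baseline** cohort mean/SD
with timed measures negated so higher is always better. Baseline-norm
scoring at all visits (rather than per-visit re-standardization) is the
standard longitudinal choice: it leaves cohort decline visible as
negative drift and is flagged here as an assumption since the source
protocol does not state it. A compound with any missing constituent is
missing — the mixed model absorbs missingness; nothing is imputed.

## The longitudinal model

For subject $i$ with observed visit vector $y_i$,
$y_i \sim N(X_i\beta, \Sigma[o_i, o_i])$: visit year is a 4-level
categorical factor with sum-to-zero contrasts, so the volume main
effect is its average effect across visits (fitted with the interaction
present); predictors enter as $\log(V + \varepsilon)$ with
$\varepsilon$ one voxel volume (0.024 cm³), the smallest measurable
nonzero volume. $\Sigma$ is estimated by REML over its log-Cholesky
factor (unconstrained, hence always positive definite) with $\beta$
profiled out by GLS; per-pattern visit-pair cross-products are
precomputed so one deviance evaluation is $O(m^2 p^2)$ regardless of
cohort size. Numerical safeguards: the deviance refuses condition
numbers beyond $10^{10}$ in $\Sigma$ and negative profiled residual
sums (both regions where cancellation can make the criterion spuriously
unbounded below), and a fit is only flagged converged when the BFGS
exit is clean and the gradient norm is small relative to the deviance.

Tests use Wald statistics with Satterthwaite denominator degrees of
freedom computed from the REML covariance of the covariance parameters
(delta method per contrast; multi-df contrasts combine per-eigenvector
df). The interaction is the 3-df test of the volume-by-time
coefficients; per-year effects are main + year deviation with Wald SEs.
Time-as-factor and Satterthwaite are both stated assumptions:
repeated-measures analyses of this design report per-year effects, and
Satterthwaite is the usual default in the standard software for them.
α = 0.05 two-sided without multiplicity correction matches common
practice in clinical longitudinal studies; it is a design-emulation
choice, not a recommendation. On 500 null cohorts of 100 subjects the 3-df
interaction test rejects at 5.0%.

The closed-form identity used as an oracle: on balanced complete data
under saturated time means, the REML $\hat\Sigma$ equals the sample
covariance of subject visit-vectors with denominator $n-1$; the fit
reproduces it to $10^{-8}$. In the homoscedastic limit (forcing
$\Sigma = \sigma^2 I$) the GLS coefficients equal OLS exactly. An
independent GLS implementation (`nlme::gls` with `corSymm` +
`varIdent`) agrees with the fitted $\hat\Sigma$ and $\hat\beta$ on
incomplete data; it is a cross-check only, never the implementation.

## Problem sizes and reproducibility

All randomness flows through explicit seeds; per-stage and per-subject
seeds derive from one master seed by fixed offsets, so stages are
independently reproducible and two pipeline runs with the same master
seed are hash-identical file by file. The shipped checks use: one
default phantom (96 × 96 × 24) for segmentation quality and
partial-volume recovery; 20 growth phantoms at the
default geometry for progression enrichment; 500 simulated cohorts
(n = 100) per point of the calibration/power curve; 200 cohorts
(n = 200, 30% MAR dropout) for effect recovery; and a 12-subject
pipeline (48 × 48 × 16 at 4 × 4 × 7.5 mm) for end-to-end determinism.
These sizes are the package's chosen compromise between Monte-Carlo
error and desk-scale runtime.

## Known limitations

The discriminative clustering instantiation here — objective,
optimizer and probability calibration — is the package's own, chosen
for testability; other instantiations of the same idea will differ in
detail. The conventional-segmentation surrogate stands in for semi-automated
operator marking. Interslice gaps are recorded as metadata but not
counted in volumes (slice thickness only — conservative and explicit).
Registration, skull stripping and bias-field correction of real data
are out of scope: mismatched grids are refused, never resampled.
Phantom simplicity means segmentation accuracies reported by the test
suite should be read as upper bounds relative to clinical data.
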