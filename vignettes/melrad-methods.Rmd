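---
title: "Methods: PET radiomic modelling of one-year progression-free status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET radiomic modelling of one-year progression-free status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melrad)
```

## The problem and the model

Metastatic cutaneous melanoma treated with first-line immune checkpoint
inhibitors shows highly variable response: a large fraction of patients
progress within the first year. The pipeline in this package builds a
pre-treatment FDG-PET radiomic classifier of **one-year progression-free
status** (1y-PFS: progression or death within 12 months of treatment start)
from baseline tumour texture, then asks whether the classifier stratifies
progression-free and overall survival.

The statistical model is deliberately conventional at every standard step
and explicit where choices were open. The stages and their assumptions:

1. **Liver-referenced segmentation.** Tumour voxels are those with
   SUV ≥ `1.5 · μ_liver + 2 · σ_liver`, the PERCIST-style lesion threshold,
   with liver statistics taken over a 3-cm spherical VOI. The assumption is
   that hepatic background uptake is a stable per-patient reference; the
   threshold therefore adapts to injected dose and scanner calibration.
2. **Texture radiomics on wavelet sub-bands.** Higher-order texture on
   band-pass filtered images captures spatial heterogeneity that first-order
   SUV summaries miss. The working assumption of the downstream model is
   only that *some* of the 856 features carry outcome signal.
3. **Location/scale batch harmonization.** Feature distributions differ by
   centre/scanner; an empirical-Bayes location/scale adjustment
   (reference-batch ComBat) is assumed sufficient, i.e. batch effects are
   additive/multiplicative per feature and biological signal is orthogonal
   to centre.
4. **Screen-then-model.** Unadjusted Mann-Whitney screening plus Spearman
   redundancy pruning control dimensionality before any model sees the data;
   the MLP assumes only smooth non-linear interactions among the few
   survivors.
5. **Proportional hazards** for the survival endpoints, with Efron tie
   handling and Wald intervals — standard clinical reporting.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| resample target | 1 | mm | isotropic grid before texture analysis |
| liver VOI diameter | 30 | mm | hepatic reference sphere |
| threshold rule | 1.5·μ + 2·σ | SUV | liver-referenced lesion threshold |
| min component size | 64 | voxels (mm³) | suppress noise specks; configurable |
| bin width | 0.1 | SUV | fixed-width discretization, all image types |
| wavelet | coif1, 1 level | — | undecimated, shape-preserving sub-bands |
| screen α | 0.05 | — | unadjusted exploratory retention level |
| redundancy ρ_max | 0.7 | Spearman | greedy keep-first-by-p pruning |
| split | 60/40 | — | training vs validation, stratified |
| CV folds | 10 | — | stratified, within the training split |
| hidden units | 4 | — | single hidden layer; small final models |
| weight init offset | ±0.5 | — | uniform around 0 |
| regularization λ | 5e-7 | — | optimizer weight decay |
| threshold grid | 0.005 | probability | EFF scan step; smallest-max tie rule |
| 1y cutoff | 12.0 | months | inclusive of events at exactly 12.0 |
| Cox entry p | 0.20 | — | univariable screen into the multivariable model |

## Design choices where the design was open

**Sphere membership and SD.** Voxels belong to a sphere when their centre is
within the radius, inclusively; the liver SD is the population SD. Both
choices are arbitrary but unambiguous and testable.

**Threshold comparisons.** Segmentation keeps voxels with SUV ≥ T
(inclusive); classification calls a patient positive when the predicted
probability is *strictly* above the operating threshold (the ">55%"
convention). Connectivity is the 26-neighbourhood.

**Merged tumour mask.** All lesions of a patient are merged into one region
for feature extraction. Computing per-lesion features and aggregating is a
defensible alternative; the merged mask was chosen because it needs no
aggregation rule and matches whole-burden texture reading.

**Wavelet transform.** Single-level *undecimated* (stationary) separable
coif1 transform with periodic boundary handling, implemented by FFT circular
convolution with centred filters. Undecimated sub-bands keep the grid shape,
so the original lesion mask applies unchanged to every sub-band — the
property the whole sub-band feature design relies on. Sub-band letters
follow array axis order (first letter = filter along the first array
dimension). Axes shorter than the 6-tap filter support wrap periodically
rather than failing. Reconstruction by conjugate filtering is exact for
orthogonal filters and is used as the transform's oracle.

**Registry composition.** The published total of 856 features is the only
stated fact about the registry. The composition used here — 93 features
(18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) × 9 image
types, plus 14 shape and 5 extra first-order features on the original image
— reaches that total with standard class sizes. The 14 shape features use
the voxel-face surface area (not a mesh) and principal-axis lengths from the
coordinate covariance; the 5 extras are StandardDeviation,
CoefficientOfVariation, MedianAbsoluteDeviation,
QuartileCoefficientOfDispersion and TotalLesionGlycolysis (mean SUV × volume
in ml) — PET-typical summaries computable from the in-mask values.

**Texture conventions.** Distance-1 offsets; per-direction features averaged
over the 13 unique 3D directions (GLCM symmetric); discretization anchored
at each image's in-mask minimum (the bin origin is not stated anywhere, and
anchoring at zero would break on the signed wavelet sub-bands); GLDM
dependence tolerance α = 0 with dependence size counted including the centre
voxel so size-weighted features stay defined; degenerate regions (too few
voxels for a matrix) return 0 with a warning. Entropies use log2 with a
machine-epsilon guard. Two features get an explicit degenerate-value guard:
Imc2 and MCC are exactly 0 on independence/rank-1 co-occurrence structure,
but the closing square root amplifies one-ulp cancellation noise to ~1e-8,
so sub-1e-12 arguments are clamped to 0.

**Harmonization scope.** `combat_fit()` takes the combined table and anchors
the standardization to the reference centre, which stays an exact fixed
point; `combat_apply()` then adjusts any table with known batch labels. The
fit can include the testing centre's *features* (never its outcomes) — this
is the default, mirroring the "a posteriori" procedure; a plain
location/scale variant (`method = "ls"`) is provided, which is exactly
idempotent, whereas the empirical-Bayes route leaves per-feature shrinkage
residuals of order `1/√n`. No biological covariates enter the design matrix.

**Screen details.** The Mann-Whitney test is exact when both groups have
≤ 20 observations and no ties, otherwise the normal approximation with tie
and continuity correction. The redundancy pass is greedy in ascending-p
order with lexicographic tie-breaking: the ambiguous "keep the most
significant of a correlated pair" rule is realized as keep-first-by-p, and
every discarded pair is logged so alternative readings can be compared.
Selection sees the development cohort only.

**Model building.** The hidden-layer width is not derivable from the
published description; 4 units is the default (small cohorts, 3-feature
final models), configurable. "Importance" of the original software node is
undocumented; permutation importance on out-of-fold data (20 shuffles per
feature, log-loss increase, ranks averaged over folds) is the reproducible
proxy. The optimizer is the standard quasi-Newton fit of a softmax MLP
(`nnet`) with weight decay 5e-7 and uniform ±0.5 initialization, restarted
from several seeded initializations and keeping the best training loss; this
substitutes for a scaled-conjugate-gradient optimizer and passes the same
separability oracles (XOR with 4 hidden units, near-Bayes AUC on separated
Gaussians). The 10 folds partition the 60% training split; the 40%
validation split is used only for EFF-based size/threshold selection. EFF
ties resolve to the smaller feature set, then to the smaller threshold.

**Synthetic cohorts.** The generator emulates the two-centre design: 95 and
59 patients with 1-year event probabilities 0.484 and 0.407 (the published
cohort rates), 100 standard-normal features with 3 planted signal features
(standardized shift 1.0 between progressors and non-progressors — a
moderate, recoverable effect at these sample sizes), and centre-2 batch
effects γ = 0.5, δ = 1.5 (a visible scanner effect; the study reports no
per-centre feature distributions, so these are free parameters). Survival
times come from an exponential proportional-hazards model on the latent
1-year-risk indicator (baseline hazard 0.03/month, log-HR 1.5, chosen so the
median time to early progression is a few months as in the published
cohorts), truncated to ≤ 12 months for 1-year progressors and shifted past
12 months otherwise, so the status/time consistency invariant holds *by
construction*; dropout censoring is uniform on (12, 36) months so every
1-year event is observed; OS adds an exponential post-progression increment
(mean 8 months), so OS ≥ PFS always. Phantom lesions use a lognormal
speckle multiplier (σ = 0.15 log-SUV) so texture-variance features are
non-degenerate.

What the generator does *not* emulate: realistic anatomy or PET physics
(no partial-volume, attenuation or reconstruction effects), correlated
feature blocks, non-linear batch effects, informative censoring, or any
coupling between clinical covariates and outcome. Passing tests therefore
demonstrate that the pipeline recovers the structure it assumes — planted
location shifts, proportional hazards, additive/multiplicative batch effects
— not that it would perform comparably on real multi-centre PET data.

## Numerical choices

* All randomness flows through explicit integer seeds; package functions
  save and restore the caller's RNG state, so results are bit-reproducible
  and never depend on ambient state.
* Empirical-Bayes iteration: convergence tolerance 1e-6, at most 100
  iterations; features with zero reference variance are flagged, passed
  through unharmonized and excluded from the shrinkage pooling; a constant
  feature inside a non-reference batch keeps a strictly positive shrunken
  scale, so the transform stays finite.
* Stratified folds allocate per-class remainders to the currently smallest
  folds, so fold sizes differ by at most one overall.
* Ties: feature-importance ties break lexicographically by identifier;
  EFF threshold ties take the smallest grid value; screen p-value ties order
  lexicographically.
* Degenerate inputs: an empty segmentation is a warning plus an empty
  result, not an error; single-voxel texture regions fall back to 0 with a
  warning; evaluation with a single observed class reports NA for the
  undefined ratios rather than silently zeroing them.

## Problem sizes used by the test-suite

Texture oracles run on 50 random 4×4×4 regions; selection and recovery
properties use 20 seeds at the study's cohort sizes (95/59 patients, 50–100
features); Cox recovery averages 50 seeds at n = 95; the end-to-end
pipeline checks run the full default configuration (including the imaging
stage on a 40³ phantom) twice and compare bit-for-bit. These sizes make the
whole suite run in a couple of minutes while leaving every statistical
assertion at the cohort scale the design targets.

## Known limitations

* The published model's headline numbers (development AUC 0.74, the 55%
  threshold, the 46 → 3 feature counts, the stratified hazard ratios) are
  functions of the original registry data, which are not public; this
  package reproduces the *procedure* and the printed-arithmetic checks, not
  those data-dependent values.
* The published development efficiency of 50.5% is not consistent with the
  printed sensitivity, specificity and prevalence under the stated EFF
  formula (which gives ≈ 0.62); `efficiency()` implements the formula.
* Surface area uses voxel faces, which overestimates a mesh surface area;
  shape features are internally consistent but not mesh-comparable.
* The MLP is a small fully-connected network; with the default 4 hidden
  units and heavy feature pre-reduction it is robust, but it is not the
  original SPSS Modeler node, and importance ranks are a proxy.
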