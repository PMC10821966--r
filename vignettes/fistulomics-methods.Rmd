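---
title: "Predicting radiotherapy-induced esophageal fistula from multi-VOI radiomics and dosiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting radiotherapy-induced esophageal fistula from multi-VOI radiomics and dosiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Esophageal fistula (EF) is a severe complication of radiotherapy for
esophageal cancer: an abnormal channel from the esophagus into the
mediastinum or airway, carrying a median survival of months once it occurs.
Predicting which patients are at risk *before* treatment would let clinicians
adapt dose, nutrition and surveillance. The hypothesis this package
operationalizes is that EF risk is encoded jointly in the pre-treatment CT
appearance (radiomics) and in the planned 3D dose distribution (dosiomics),
and that features should be read from several volumes of interest at once:
the esophagus organ (ESO), the gross tumor volume (GTV), and their union
(EG), because the fistula forms where tumor and organ wall interact.

`fistulomics` implements the complete analysis as a reusable, tested
pipeline: feature extraction, stability-based feature selection, ridge
classification under repeated stratified splits, model comparison, and
decision-curve analysis — together with a synthetic cohort generator so
every stage can be exercised and validated without patient data.

## Feature extraction

**Radiomics.** For each VOI the package computes 14 three-dimensional shape
features once on the mask, plus 18 first-order and 73 texture features for
every combination of derived image and gray-level count. The derived images
are the original CT, three Laplacian-of-Gaussian images (sigma = 1, 3, 6 mm,
computed in physical units with mirror boundaries) and the 8 sub-bands of a
single-level 3D stationary wavelet transform. Intensities are discretized to
a fixed number of bins spanning the ROI range (10, 20, 30, 40, 50 by
default), which makes every texture feature invariant to positive affine
intensity maps. The default configuration therefore yields
`14 + 12 * 5 * (18 + 73) = 5474` features per VOI, and the counting identity
`14 + images * bins * 91` holds for any configuration.

Design notes, where the convention was genuinely open:

* *Wavelet.* An undecimated (stationary) coiflet-1 transform with circular
  boundary handling. The filter pair is orthonormal, so the transform has
  exact perfect reconstruction — asserted in the test suite at 1e-6 relative
  error, and in practice exact to rounding.
* *Texture set.* The 73 texture features are 22 GLCM + 16 GLRLM + 16 GLSZM +
  14 GLDM + 5 NGTDM. The GLCM family is the canonical 24-member list minus
  SumAverage (identically twice JointAverage on symmetric matrices) and MCC;
  only the count, not the membership, is fixed by the modelled protocol, so
  the exclusion pair is a documented default. GLCM and GLRLM use the 13
  unique 3D directions at distance 1, features averaged unweighted over
  directions with at least one pair.
* *Shape surface estimators.* `SurfaceArea` uses the voxel-face convention
  (a single unit voxel reports 6 mm²). That convention overestimates smooth
  surfaces by ~3/2, so `Sphericity` instead combines the marching-tetrahedra
  mesh volume with a coarea surface estimate (the integrated gradient
  magnitude of the Gaussian-smoothed indicator, sigma = 1.5 × min spacing),
  which converges for smooth shapes: a digitized sphere of radius 20 voxels
  scores > 0.97. Sphericity is clamped at its isoperimetric bound of 1.
  Degenerate masks (single voxel) return defined values rather than errors.
* *No resampling stage.* Features are computed on the native lattice; the
  synthetic generator emulates clinical anisotropy (3 mm slices) directly.

**Dosiomics.** Three families per VOI, 213 features under the defaults:

* *DVH parameters.* `Dx` is the minimum dose received by the hottest x% of
  the VOI volume (linear interpolation on the descending sorted voxel
  doses); `Vx` is the VOI fraction receiving strictly more than x Gy. The
  default grids are Dx at {0.5, 0.8, 1, 2, 5 .. 90 by 2.5} (39 points; D0.8
  is included because near-maximum esophageal doses are prognostic) and Vx
  at {4 .. 80 by 4} Gy (20 points). The printed total of 213 fixes only
  `|Dx| + |Vx| = 59`; the split is a configurable default.
* *Scale-invariant 3D dose moments.* Dose-weighted central spatial moments
  over physical coordinates, with each voxel weighted by dose × voxel
  volume, normalized as `eta_pqr = mu_pqr / mu_000^(1 + (p+q+r)/3)`. All 63
  order triples (p,q,r) in {0..3}³ except (0,0,0) are reported. The
  volume-integral weighting is what makes the normalization exponent cancel
  isotropic spatial scaling exactly (asserted at 1e-9 relative); centering
  gives translation invariance by construction.
* *Dose-based radiomics.* The shared first-order + texture extraction (91
  features) applied to the raw dose map, original image only.

## Feature selection

Selection follows a stability-screening design. Within a training cohort:

1. standardize to zero mean and unit (population) variance;
2. draw 100 stratified subsamples of 70% without replacement;
3. in each, drop zero-variance columns and keep features with a two-sided
   equal-variance Student t-test p < 0.01 against the EF label;
4. compute each feature's selection frequency `f_i = sum(x_i) / 100`;
5. keep the top `max(ceil(10% of survivors), 40)` by frequency (ties broken
   by mean |t|, then name, for determinism);
6. prune redundancy greedily in frequency order at |Pearson r| > 0.5;
7. evaluate the nested prefixes (top-1, top-2, ..., top-K) with the ridge
   classifier and keep the prefix with the best evaluation-cohort AUC
   (ties to the smaller subset).

Two points deserve flagging. The "combinations ranging from 1 to the number
of reserved features" are implemented as nested frequency-ranked prefixes:
the power set is intractable for K ≈ 40 and inconsistent with a 1..K range.
And the modelled protocol selects the prefix on the *testing* cohort, which
leaks test information into the subset size. The default reproduces that
protocol; `subset_selection = "nested"` replaces it with an inner split of
the training cohort and is what the null-calibration test uses — under
label permutation the nested pipeline's mean test AUC over 10 repeated
splits stays within 0.5 ± 0.1.

Under a permuted-label null the per-resample keep rate approximates the
screening threshold (~1%), a property-tested sanity check on the screen.

## Models and evaluation

Nine feature groups are assembled — {ESO, GTV, EG} × {R, D, RD} — with RD
the column concatenation of a VOI's radiomics and dosiomics blocks. EG
features are by default extracted on the union mask (EG as a VOI, matching
its anatomical definition); `eg_mode = "concat"` instead concatenates the
ESO and GTV feature sets, a reading suggested by per-VOI attributions of
selected features inside combined models. Both modes are supported; union
is the default.

The classifier is "ridge": L2-penalized logistic regression fitted by IRLS,
with the penalty chosen from 13 log-spaced values in 1e-3..1e3 by stratified
10-fold cross-validation maximizing the pooled out-of-fold AUC (pooling
keeps the criterion defined when folds hold only a few patients; the fold
count is capped at the per-class sample count for small cohorts). A
ridge-regression-on-labels variant is available behind `family = "linear"`
since the bare name "Ridge" admits either; the logistic form is the default
because threshold metrics and decision curves need probabilities. An
independent check against glmnet at matched penalty scaling is part of the
test suite.

Each model is evaluated over 30 independent stratified 7:3 splits (seeds
`seed + 0..29`); each iteration re-runs standardization, selection and
fitting from scratch on its training cohort. Reported metrics are AUC
(rank-based, ties at 0.5), accuracy, precision, recall and F1 at probability
threshold 0.5, aggregated as mean ± STD with a normal 95% CI of the mean.
AUC confidence intervals for a single cohort are available by DeLong's
placement-value method or a 2000-resample stratified bootstrap (the modelled
protocol's "DeLong with 2000 iterations" conflates the two, so both exist;
the bootstrap is the labelled default). Models are compared by two-sided
paired Student t-tests on per-iteration AUCs. Decision-curve analysis
reports `NB(t) = TP/n − (FP/n) t/(1−t)` against treat-all and treat-none
references.

## The synthetic cohort: what it emulates and what it does not

The generator states a world once and the tests live in it:

* anatomy: an axial esophageal tube (radius ~5 mm, jittered, gently curved)
  and an ellipsoidal GTV centered on it, guaranteeing tumor–organ contact;
* CT: a smoothed Gaussian random field (4 mm correlation length, 30 HU
  amplitude) plus tissue offsets and voxel noise;
* dose: an anisotropic Gaussian conformal to the GTV scaled to the
  prescription implied by the sampled fraction dose (30 × 1.8 or 2.0 Gy);
* clinical covariates drawn from the pooled category frequencies of the
  modelled 287-patient cohort's characteristics table, which doubles as the
  fixture set for the clinical statistics;
* outcome: EF ~ Bernoulli(plogis(b0 + beta·z + noise)) over standardized
  drivers computed by the real feature operations — an esophagus CT texture
  (GLCM joint entropy), esophageal high-dose coverage (V50), a craniocaudal
  GTV dose moment (eta_003) and the fraction-dose covariate — with default
  weights (1.2, 0.8, 0.8, 0.5) chosen to mirror the finding that esophagus
  radiomics dominate while dose features contribute; b0 is solved so the
  expected prevalence matches the 149/287 class balance. Default logit
  noise is 0.5.

The true clinical effect sizes are unknowable from the published record;
these defaults are illustrative, not calibrated. A green directional test
(EG-RD ≥ single-VOI RD on test AUC) therefore establishes that the pipeline
*can* pool complementary multi-VOI signal when it exists — not that the
clinical effect has any particular size. The generator does not attempt
anatomically realistic CT, Monte-Carlo dose, or inter-scanner variation.

## Numerical choices and degenerate inputs

* Constant ROIs: entropy 0, uniformity 1, skewness/kurtosis reported as 0;
  single-gray-level texture matrices give defined zeros (NGTDM coarseness
  saturates at 1e6).
* Single-voxel masks: no voxel pairs exist, so GLCM/GLRLM blocks are zero
  and shape axis lengths are 0 with elongation/flatness 1.
* Zero-variance columns standardize to 0 and are screened out.
* Prefix-search ties and CV-AUC ties resolve deterministically (smaller
  subset; stronger penalty).
* All randomness flows from explicit seeds; identical seeds give bitwise
  identical cohorts, selections and reports.
* Tests and the acceptance script run reduced configurations (fewer derived
  images, fewer iterations) where only runtime, not the property under
  test, depends on scale; every such reduction is noted inline.

## Known limitations

* The texture-feature membership behind the published count of 73 is a
  documented default, not a verified match to the original extraction.
* DICOM RT parsing, contour rasterization and grid resampling are out of
  scope; volumes must arrive on a shared lattice (NIfTI-1, axis-aligned).
* The headline clinical AUCs of the modelled study depend on its private
  287-patient cohort and are not reproducible here; this package reproduces
  the *procedure* and its verifiable structural and statistical properties.
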