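---
title: "deltarad: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deltarad: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After preoperative chemoradiotherapy (CCRT) for locally advanced rectal
cancer, the change in the tumor's appearance on T2-weighted MRI carries
prognostic information beyond either timepoint alone.  `deltarad`
implements a delta-radiomics pipeline: paired pre-/post-treatment
volumes with tumor and bladder-urine ROIs are normalized, quantized and
resampled; 55 radiomics features are extracted in 2D and 3D at each
timepoint; the per-feature difference (after minus before) is the delta
feature; features unstable under small contour shifts are discarded; a
sparse linear risk score (Rad score) is fitted by L1-penalized Cox
regression for three endpoints (local recurrence LR, distant metastasis
DM, disease-free survival DFS); and the score is evaluated with
survival machinery (log-rank at an optimal cutpoint, Cox models,
Harrell's C, AUC, Hosmer-Lemeshow, Pearson/VIF for the 2D-vs-3D
comparison).  The six published Rad-score formulas are also encoded
verbatim, so new data can be scored without refitting.

No imaging cohort is distributed.  Everything is exercised on a
synthetic cohort generator whose stated world is described below.

## Preprocessing

The chain is fixed: Collewet clip, urine normalization, isotropic
resampling, quantization.

* **Collewet clip.** In-ROI intensities are clipped to the band
  mean ± 3 SD.  The statistics are computed from the tumor ROI (not the
  whole image): the method's purpose here is tumor-signal
  standardization, and a whole-image band would be dominated by
  background.  Out-of-band voxels are clipped rather than excluded so
  the mask topology is preserved.  Both choices are arguments of
  `collewet_normalize()`.
* **Urine normalization.** Every voxel is divided by the mean intensity
  of the ~1 cm^3 bladder-urine reference mask, making the urine mean
  exactly 1 and cancelling any global intensity scale (tested property:
  the quantized ROI is invariant under `volume * k` for any `k > 0`).
* **Quantization.** `level = clamp(ceiling(64 * v), 1, 64)` with
  right-closed bins, so intensity exactly 1 — the urine mean — lands on
  level 64, `v <= 0` on level 1, and `v > 1` saturates at 64.
* **Resampling.** Intensities are resampled trilinearly to 1 mm
  isotropic voxels *before* quantization (interpolating discrete labels
  is ill-defined); masks use nearest-neighbor.  For 2D analysis the
  axial slice with the largest mask area is selected (ties to the
  lowest slice index) and resampled in-plane to 1 x 1 mm.

## Features

`extract_all()` returns 55 named features in a fixed registry order:
size (volume in mm^3, or area in mm^2 in 2D), 8 first-order statistics,
15 GLCM, 13 GLRLM, 13 GLSZM and 5 NGTDM features.  The per-family lists
follow the standard Haralick / Galloway / Thibault / Amadasun-King
definitions in their IBSI-consistent form; the registry contains every
feature named by the published formulas (`Int_Energy`,
`GLCM_SumAverage`, `GLCM_SumVariance`, `GLCM_Autocorrelation`,
`GLRLM_SRLGLE`, `GLRLM_LRLGLE`, `GLRLM_LRHGLE`, `GLSZM_LZLGLE`,
`GLSZM_LZHGLE`, `NGTDM_Coarseness`, ...).

Numerical conventions, applied consistently and tested:

* Texture matrices use displacement distance 1: 13 unique directions in
  3D (4 in 2D) for GLCM/GLRLM, 26-connectivity (8) for GLSZM zones and
  the NGTDM neighborhood.  Per-direction feature values are averaged
  (matrices are not merged); GLCM directions with no in-mask pair are
  skipped.
* Gray levels are indexed 1..64; low/high gray-level weights are
  `1/i^2` and `i^2`.
* `Int_Energy` is the **mean** of squared urine-normalized intensities,
  a size-invariant choice consistent with the O(1) coefficients it
  multiplies in the published formulas; `energy_mode = "sum"` gives the
  summed variant.
* Degenerate cases: skewness and (excess) kurtosis of a constant ROI
  are 0; entropies use `0 log 0 = 0`; GLCM correlation of a
  zero-variance matrix is 1; NGTDM coarseness is capped at `1e6` when
  its denominator falls below `1e-6` (uniform ROI).

All four texture-matrix builders are verified exactly against naive
enumeration oracles on random small ROIs, and direction-averaged
features are checked to be invariant under axis-aligned rotations.

## Delta features and robustness

The delta feature is `after - before`, elementwise over the registry.
Robustness emulates inter-observer contouring variability: the mask is
translated by ±1 voxel (= ±1 mm on the resampled grid) in each in-plane
direction — the 8 non-identity elements of `{-1,0,1}^2` — while the
image stays fixed.  Craniocaudal shifts are excluded because 2D
extraction would then see a different slice rather than a shifted
contour; `translated_rois(include_z = TRUE)` gives the axial variant.

With 9 repeats per subject (original + 8 shifts), a one-way
random-effects single-measure ICC(1,1) is computed per feature in each
of the four tables {2D, 3D} x {before, after}; features with ICC > 0.9
in **all four** are robust.  ICC(1,1) was chosen because translations
are interchangeable perturbations, not meaningful fixed raters.  A
feature whose values are identical everywhere has an undefined ICC and
is treated as non-robust.  The published analysis retained 22 robust
features; that count is data-dependent and is not a target for the
synthetic cohort.

## Signature fitting and cutpoints

`lasso_cox_fit()` minimizes the L1-penalized Cox partial likelihood
(via coordinate descent) over 100 log-spaced penalties down to
`1e-3 * lambda_max`, choosing the penalty at minimum mean
cross-validated partial-likelihood deviance (10 folds, fold assignment
stratified by event status and seeded).  Features are standardized
internally and coefficients reported on the original scale — the
published coefficients' wildly different magnitudes (1e-8 to 1e2)
indicate original-scale reporting.  The minimum-CV rule, not the 1-SE
rule, matches the stated selection; a consequence (measured by the
acceptance suite) is that under pure noise the fitted signature is
empty only ~60% of the time, since min-CV occasionally prefers a small
spurious model.

`optimal_cutoff()` scans midpoints between consecutive sorted unique
scores and maximizes the two-group log-rank chi-square, with an
admissibility floor of 10% of patients (never fewer than 2) per group —
a guard the source analysis does not state but which prevents
degenerate one-patient groups; ties go to the lower cutoff.

## Evaluation

* **Harrell's C** uses event-anchored comparable pairs (ties in score
  count 0.5) with an influence-function standard error; it agrees with
  brute-force pair enumeration exactly and with
  `survival::concordance()` numerically.
* **2D-vs-3D comparison**: Pearson r with Fisher-z CI and
  `VIF = 1/(1 - r^2)`; C-indices are compared by a paired patient
  bootstrap (1000 replicates, normal approximation), chosen for
  distribution-freeness since the source does not name its test.
* **AUC / Hosmer-Lemeshow** target binary event occurrence ignoring
  censoring times — the source does not define its ROC construction for
  censored endpoints, so this is a documented caveat, not a claim of
  equivalence.  The raw Rad score is not a probability, so HL is
  computed after a univariate logistic recalibration, on deciles, with
  g - 2 df.
* Cox tables (univariate, and multivariate over univariate-significant
  covariates at p < 0.05) use Efron ties; collinear or non-convergent
  fits are flagged, not fatal.

## The synthetic cohort: what it states and what it does not

`cohort_config()` defaults define the stated world:

* Native grid 16 x 80 x 80 voxels at 4 x 0.5 x 0.5 mm — the anisotropic
  axial geometry of the emulated protocol (4 mm slice spacing,
  sub-millimeter in-plane).
* Tumor: ellipsoid with base radius U(8, 15) mm and per-axis
  anisotropy U(0.85, 1.15), filled with a Gaussian random field
  (white noise smoothed by an isotropic Gaussian, correlation length
  2 mm, intensity SD 25% of the tumor mean).  Smoothed correlated
  noise was chosen because its correlation length monotonically drives
  NGTDM coarseness and GLCM energy — the features the published
  signatures lean on (tested: mean coarseness increases with
  correlation length).
* Bladder: a 1 cm^3 sphere (radius 6.2 mm) of bright, nearly constant
  intensity (SD 1% of its mean), the normalization reference.
* Latent response `r ~ Beta(2, 2)` acts on three knobs: tumor scale
  `1 - 0.5 r`, correlation-length multiplier `1 + r` (residual tissue
  homogenizes), intensity-SD multiplier `1 - 0.5 r`.  All noise draws
  are shared between timepoints, so `r = 0` reproduces the before image
  exactly and the after-tumor volume is non-increasing in `r`.
* Outcomes: exponential event times with rate
  `h0 * exp(score)`, administrative censoring at 60 months plus uniform
  dropout with probability 0.25.  Endpoint baselines
  (LR 0.003, DM 0.005, DFS 0.025 per month) reproduce the clinical
  ordering (DFS events dominate, LR is rare) and give ~30% censoring
  for DFS.  The score is built from standardized 3D delta features with
  weights `(Int_Energy: +1, NGTDM_Coarseness: -1)`.  The signs matter:
  response *lowers* delta energy and *raises* delta coarseness, making
  the two strongly anti-correlated (r ~ -0.8); equal positive weights
  would nearly cancel and state an incoherent "strong effect" world.
  With the coherent signing a high score reads as "non-responder" and
  carries higher hazard.

What the generator does **not** emulate: bias fields, scanner/protocol
heterogeneity, motion or susceptibility artifacts, irregular tumor
shapes, DWI guidance, or any real post-CCRT signal physiology — the
response-to-texture mapping is a modeling choice, since the source
describes post-treatment appearance only qualitatively.  A green
end-to-end test therefore establishes that the pipeline recovers a
planted proportional-hazards delta-feature signal at realistic n and
censoring; it says nothing about clinical validity on real MRI.

## Numerical and degenerate-input policy

Voxel arrays are ordered `(z, y, x)` everywhere; axial slices index z;
spacing vectors share the order, in mm.  Masks that empty under
resampling, translations that exit the grid, empty ROIs, zero-variance
scores, single-class AUC inputs and zero-event fits all raise
structured errors naming the offending stage or dimension.  Volumes and
masks travel as NIfTI-1 (a minimal built-in codec: one 3D scalar
volume, spacing in `pixdim`, identity sform), tables as CSV, signatures
and reports as JSON at full precision.

## Known limitations

* The exact per-family feature lists of the source's appendix are not
  public; the registry is the standard set matching the printed counts
  and containing every printed signature term.  Where a definition has
  variants (e.g. GLCM correlation normalization) the IBSI form is used.
* ICC(2,1) is available as an option but ICC(1,1) is the default and
  the only filtered form.
* The minimum-CV-error penalty rule makes null-data sparsity a coin
  toss near the 60% level by construction; the 1-SE rule would be
  sparser but is not what the stated selection uses.
* Patient-level results of the source (C-indices ~0.79-0.89, r =
  0.64-0.84, the 22-feature robust set) depend on 101 real MRI studies
  that are not deposited; they are encoded as inputs (the published
  formulas) or used as worked examples (VIF), never re-derived.
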