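# deltarad

Delta-radiomics survival signatures from paired pre-/post-treatment MRI
of rectal cancer.

## What it does, and for whom

After preoperative chemoradiotherapy (CCRT) and surgery for locally
advanced rectal cancer, the *change* in the tumor's T2-weighted MRI
appearance is prognostic.  `deltarad` is for imaging and biostatistics
researchers who want a tested, reproducible implementation of that
delta-radiomics workflow:

1. **Preprocess** paired volumes: Collewet mean ± 3 SD clipping, division
   by the mean bladder-urine intensity (so urine = 1), 64-level
   quantization with the urine mean on the top level, isotropic 1 mm
   resampling (3D) or largest-axial-slice selection at 1 × 1 mm (2D).
2. **Extract 55 features** per ROI and dimensionality: volume/area, 8
   first-order statistics, 15 GLCM, 13 GLRLM, 13 GLSZM and 5 NGTDM
   texture features (Haralick / Galloway / Thibault / Amadasun–King,
   IBSI-consistent; compiled texture kernels, verified against naive
   enumeration oracles).
3. **Delta features**: Δf = f(after) − f(before).
4. **Robustness filter**: features are re-extracted from the original
   ROI and its 8 in-plane ±1 mm translations; a feature is kept only if
   its one-way single-measure ICC(1,1) exceeds 0.9 in all four tables
   {2D, 3D} × {before, after}.
5. **Signature**: LASSO-Cox on the robust delta features, with the
   penalty chosen at minimum 10-fold cross-validated partial-likelihood
   deviance; the Rad score is the sparse linear combination

   `Radscore = Σ_j β_j · Δf_j`  (no intercept),

   dichotomized at the cutpoint maximizing the log-rank χ².  The six
   published formulas (LR/DM/DFS × 2D/3D) ship encoded digit-for-digit:
   e.g. `DM 2D = 0.4580866 · ΔInt_Energy − 45.2277485 · ΔNGTDM_Coarseness`.
6. **Evaluation**: Kaplan–Meier/log-rank, Cox tables, Harrell's C ± SE
   with paired-bootstrap comparison, AUC, Hosmer–Lemeshow, Pearson r and
   VIF = 1/(1 − r²) for the 2D-vs-3D comparison.

Because no imaging cohort is public, the package includes a first-class
synthetic-cohort generator: anisotropic (4 × 0.5 × 0.5 mm)
T2-weighted-like volumes with a textured ellipsoidal tumor whose size
and texture respond to a latent treatment response, a ~1 cm³ bright
bladder reference sphere, and proportional-hazards outcomes for
LR/DM/DFS driven by standardized 3D delta features.  See the methods
vignette (`vignettes/deltarad-methods.Rmd`) for the stated world and
every numerical convention.

## Worked example

```r
library(deltarad)

cfg <- cohort_config(n_patients = 30, seed = 42)   # stated-world defaults
ch  <- generate_cohort(cfg, keep_images = FALSE)   # images -> 3D delta features

oc <- subset(ch$outcomes, endpoint == "DFS")
X  <- ch$delta3d
oc <- oc[match(rownames(X), oc$patient_id), ]
sp <- split_cohort(rownames(X), c(2, 1), seed = 42)
tr <- rownames(X) %in% sp$training

sig <- lasso_cox_fit(X[tr, ], oc$time[tr], oc$event[tr],
                     fit_config(seed = 42), endpoint = "DFS", dims = "3D")
sig
#> <rad_signature> DFS 3D (fitted), 5 term(s)
#>   +0.008670506 x GLRLM_HGLRE
#>   +0.06776352 x GLRLM_GrayLevelVariance
#>   +1.898182 x GLSZM_SAE
#>   +0.0006927876 x GLSZM_SAHGLE
#>   -3.577816 x NGTDM_Coarseness

sc  <- rad_score(sig, X)
optimal_cutoff(sc[tr], oc$time[tr], oc$event[tr])
#> $cutoff [1] -0.7196...   $chisq [1] 15.34   $p [1] 8.96e-05

c_index(sc[!tr], oc$time[!tr], oc$event[!tr])
#> $C [1] 0.786   $se [1] 0.129
```

The fitted 5-term signature separates training outcomes (log-rank
p ≈ 9e-05 at the optimal cutpoint) and ranks held-out patients with
C ≈ 0.79 — the planted delta-feature effect is recovered.  Scoring with
a published formula needs no fitting:

```r
unit <- setNames(rep(0, 55), feature_registry())
unit["Int_Energy"] <- 1
rad_score(published_signature("DM", "2D"), unit)
#> [1] 0.4580866
```

## Command line

```sh
Rscript inst/cli/deltarad.R run-all --n 30 --seed 7 --out run/
Rscript inst/cli/deltarad.R simulate --n 10 --seed 7 --out cohort/
Rscript inst/cli/deltarad.R extract --image img.nii.gz --tumor t.nii.gz \
        --bladder b.nii.gz --dims 3d --out features.csv
Rscript inst/cli/deltarad.R score --published --endpoint DM --dims 2d \
        --delta delta.csv --out scores.csv
```

Subcommands: `simulate`, `preprocess`, `extract`, `delta`, `robustness`,
`fit`, `score`, `evaluate`, `run-all`.  Volumes/masks are NIfTI
(`.nii.gz`), tables CSV, signatures/reports JSON.

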