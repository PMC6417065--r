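Package: deltarad
Title: Delta-Radiomics Signatures for Longitudinal MRI of Rectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating delta-radiomics survival
    signatures from paired pre- and post-chemoradiotherapy MRI volumes.
    Implements bladder-urine referenced intensity normalization with
    Collewet clipping, 64-level quantization, isotropic resampling, 2D and
    3D extraction of 55 radiomics features (size, first-order, GLCM, GLRLM,
    GLSZM, NGTDM), delta features, a translated-ROI intraclass-correlation
    robustness filter, LASSO-Cox signature fitting with optimal-cutpoint
    dichotomization, and survival evaluation (Kaplan-Meier/log-rank, Cox
    models, Harrell's C with paired bootstrap comparison, AUC,
    Hosmer-Lemeshow, Pearson/VIF). Ships a synthetic-cohort generator that
    emulates T2-weighted-MRI-like tumors whose texture and size respond to
    treatment, so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    survival,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
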