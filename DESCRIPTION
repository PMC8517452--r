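Package: pcarad
Title: Radiomics Characterization of Prostate Cancer Aggressiveness from
    Multiparametric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automatic characterization of prostate cancer
    aggressiveness from co-registered multiparametric MRI (T2-weighted
    images, apparent diffusion coefficient maps, contrast-uptake maps and
    voxel-wise malignancy-probability maps). Implements rule-based
    lesion-candidate detection, an IBSI-style 92-feature 3D radiomics
    vector (intensity statistics, grey-level co-occurrence and run-length
    texture features averaged over the 13 directions of a 3D image),
    two-stage feature selection (correlation pruning plus an AUC-ranked
    wrapper with cross-validated overfitting-point detection), a
    polynomial-kernel support vector classifier emitting a calibrated
    radiomics score, dual ROC cutoffs (Youden index and maximal negative
    predictive value) and three-tier aggressiveness banding. A seeded
    synthetic phantom generator provides test substrates for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    pROC,
    jsonlite,
    graphics,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
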