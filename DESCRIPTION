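Package: lesionminer
Title: New-Lesion Segmentation from Longitudinal FLAIR MRI with a
    Patch-Based 3D UNet and Online Hard Example Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for segmenting new multiple sclerosis
    lesions from two co-registered longitudinal FLAIR volumes. Provides a
    synthetic longitudinal volume generator emulating the task's extreme
    voxel class imbalance, NIfTI preprocessing (isotropic resampling,
    per-image z-score normalization, two-timepoint channel stacking), a
    compact group-normalized 3D UNet trained patch-wise with either fixed
    positive-patch oversampling or online hard example mining scored by an
    exponential-moving-average mining network, sliding-window inference
    with overlap averaging, and lesion-level evaluation (connected
    components, minimum-volume filtering, parameterized detection
    matching, Dice/Sens/PPV/F1 with cohort mean and standard error).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
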