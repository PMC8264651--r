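Package: fltrad
Title: Early-Response Radiomics for Paired FLT-PET Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for early response assessment in neoadjuvant chemotherapy
    from paired 18F-fluorothymidine PET scans. Provides synthetic paired-cohort
    generation with known ground truth, SUV statistics and IBSI-style radiomic
    texture features (GLCM, GLRLM, GLSZM, GLDZM, NGLDM, NGTDM and
    intensity-volume histogram families) on isotropically resampled volumes,
    contour-perturbation robustness screening via intraclass correlation,
    EORTC PET response classification against residual-cancer-burden pathology,
    and L1-penalized logistic response models tuned by leave-one-out
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
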