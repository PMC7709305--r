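Package: oarseg
Title: Strategies for Improving CT Organ-at-Risk Segmentation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for systematically exercising strategies that improve
    deep-learning segmentation of low-contrast organs-at-risk on CT, with the
    salivary glands (submandibular and parotid) as the paradigm. Provides the
    standard preprocessing chain (organ-centred region-of-interest cropping,
    Hounsfield-unit windowing, normalisation), traditional and CT
    domain-specific data augmentation (elastic deformation with affine jitter,
    body and organ density shifts), Dice-based cost functions including
    true-positive down-weighting and a combined Dice plus Hausdorff cost,
    patient-specific Hounsfield-window grid search, cut-off based model
    ensembling, a compact 3D fully-convolutional training backend, a synthetic
    CT phantom generator with exact ground-truth masks, and a six-fold
    cross-validated experiment runner, so every strategy can be studied end to
    end at desk scale without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    rlang,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
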