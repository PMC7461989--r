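Package: petresponse
Title: Predicting Intra-Treatment PET Image Outcomes from Pre-Treatment
    PET/CT and Planned Dose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting intra-treatment 18F-FDG PET image outcomes
    of radiotherapy from pre-treatment PET/CT images and the planned spatial
    dose distribution, using a small all-convolutional regression network
    trained with a region-of-interest weighted mean-square-error loss.
    Includes a digital phantom generator with a known analytic dose-response
    (so every pipeline stage is testable without clinical data), NIfTI volume
    input/output with resampling onto a common grid, [0,1] intensity
    normalization with exact restoration, and the standard evaluation suite
    for PET predictions: region mean standardized uptake values (SUV), Otsu
    high-uptake subregion analysis, and 2D/3D SUV gamma tests with
    distance-to-agreement criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
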