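Package: olivemorph
Title: Three-Dimensional Morphometric Phenotyping and Variety
    Classification of Olive Drupes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating olive (Olea europaea) cultivars from
    the three-dimensional morphology of the fruit, stone and internal stone
    cavity, as imaged by X-ray micro-computed tomography.  Provides a
    synthetic-data module (variety trait profiles, seeded voxel phantoms
    with ground truth), hierarchical Otsu segmentation of mesocarp, stone
    and cavity, principal-axis alignment, extraction of continuous
    morphometric traits (volume, triangulated surface area, Wadell
    sphericity, elongation, bilateral asymmetry, position of the maximum
    transverse area, groove counting, lenticel density, rugosity),
    derivation of UPOV states of expression from continuous traits, a
    univariate battery (Tukey-Kramer pair counts from raw data or printed
    summary statistics, Pearson correlation, Mahalanobis outlier screen),
    canonical linear discriminant analysis with leave-one-out
    cross-validation, potency-index predictor ranking, Bhattacharyya
    distance/coefficient varietal overlap, and linear support-vector
    machine prediction with batch-stratified train/validation splits.
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
    jsonlite,
    Matrix,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    e1071,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
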