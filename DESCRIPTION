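Package: rccad
Title: Morphology, Texture and Enhancement-Kinetics Profiling of Renal Tumors on Multi-Phase CE-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-assisted diagnosis toolkit for renal tumors imaged with
    three-phase contrast-enhanced CT. Builds a triangulated tumor surface from a
    binary mask, maps it onto the unit sphere with an attraction-repulsion
    parameterization, and summarizes surface complexity as a 70-element
    spherical-harmonic reconstruction-error spectrum. Adds first-order histogram
    and percentile statistics, rotation-invariant 3D gray-level co-occurrence
    (Haralick) texture features, and wash-in/wash-out enhancement slopes, then
    classifies tumors in two stages (malignant renal cell carcinoma versus benign
    angiomyolipoma, then clear-cell versus non-clear-cell carcinoma) with a
    multilayer perceptron under leave-one-subject-out or stratified 10-fold
    cross-validation. Includes a seeded synthetic phantom generator so the whole
    pipeline can be exercised without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
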