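Package: fstdkit
Title: Facial Soft Tissue Depth Measurement and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for craniofacial soft tissue depth (FSTD) studies on
    CT-like intensity volumes: histogram-based segmentation of skull and skin
    surfaces, Frankfurt Horizontal Plane alignment, bone-to-skin depth
    measurement at a 23-landmark cranial registry, segmentation precision via
    sampled Hausdorff distance, observer-error statistics (TEM, rTEM,
    reliability coefficient R), age-by-sex cohort descriptives, bilateral
    asymmetry testing with bootstrap, and comparison against packaged
    reference population mean-depth tables. Includes a synthetic-data module
    generating voxel phantoms with analytically known depths and cohort
    depth tables with sex, age, asymmetry and remeasurement structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    igraph,
    car,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    knitr
Config/testthat/edition: 3
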