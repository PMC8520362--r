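Package: sonokr
Title: Kernel-Regression Reconstruction of Freehand 3D Ultrasound with
    Anal Sphincter Morphometry
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs regular intensity volumes from scattered
    freehand three-dimensional ultrasound samples by local polynomial
    kernel regression with a truncated Gaussian kernel, and derives the
    downstream pelvic-floor morphometry: clock-face thickness of the
    anal sphincter complex (internal and external anal sphincter,
    puborectalis muscle) on proximal, mid and distal axial planes, with
    two-group comparison of thickness tables by independent-sample
    t-tests from raw values or summary statistics. Includes an analytic
    digital phantom of the sphincter complex with known ground truth
    for validating the full simulate-reconstruct-measure-compare
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    data.table,
    jsonlite,
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
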