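Package: ContourQA
Title: Knowledge-Based Quality Assurance for Radiotherapy Organ-at-Risk Contours
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-class outlier detection for organ-at-risk (OAR) contour
    quality assurance in head-and-neck radiotherapy. Per-OAR single-contour
    feature models (maximum z-score, Mahalanobis distance, autoencoder
    reconstruction error) are trained on acceptable contours only, combined
    by logical OR with a contour-to-contour relationship model
    (distribution-bounded pairwise minimum distance and fractional overlap)
    and a connectedness model (disconnected-parts threshold). Includes a
    synthetic head-and-neck phantom generator with a four-category contour
    error injector (boundary, volume, non-adjacent slice, position) so the
    whole framework can be trained and evaluated without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    nnet,
    fitdistrplus,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
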