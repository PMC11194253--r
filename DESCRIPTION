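Package: cvmgrowth
Title: Mandibular Growth Staging from Cervical Vertebral Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for estimating mandibular growth stage
    (pre-pubertal, pubertal, post-pubertal) from the cervical-vertebrae
    region of serial lateral cephalograms. Computes mandibular length
    (Condylion-Pogonion) and growth velocity from longitudinal landmark
    records, anchors a three-stage gold-standard labeling to the pubertal
    velocity peak, crops and normalizes 64x64 vertebral regions of
    interest, trains a lightweight three-convolutional-layer network or an
    18-layer residual network with rotation/shift/zoom augmentation, and
    evaluates predictions with per-class one-vs-rest diagnostic measures,
    Cohen's kappa (unweighted, linear, quadratic) and the Altman
    interpretation bands. A synthetic-data module simulates growth series
    with a logistic pubertal spurt and stage-conditioned vertebra-like
    images so the whole pipeline is testable without radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
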