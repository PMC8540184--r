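Package: discseg
Title: Two-Stage Cascade Segmentation of Specific Lumbar Intervertebral Discs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Segments three specific intervertebral discs (L1/L2, L4/L5 and
    L5/S1) from 2D sagittal spine images with a two-stage cascade: a first
    encoder-decoder network segments the lower two discs on a cropped window,
    and a second network segments the upper disc on the full image augmented
    with Euclidean distance-transform feature maps computed from the lower
    discs. Includes a from-scratch MultiResUNet implementation trained with
    the focal loss, connected-component instance relabeling, an instance-aware
    evaluation protocol (IoU, per-disc discrimination criterion, image-level
    correctness and accuracy), a synthetic spine phantom generator for fully
    reproducible experiments without clinical data, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
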