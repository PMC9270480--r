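Package: mammotile
Title: Multi-Scale Tiled Inference and FROC Evaluation for Lesion
    Detection in High-Resolution Mammograms
Version: 0.1.0
Authors@R:
    person("Mammotile", "Developers", email = "mammotile@example.org",
           role = c("aut", "cre"))
Description: A detector-agnostic pipeline for finding small masses in
    ultra-high-resolution mammograms: scale-pyramid construction
    (X, 0.5X, 0.25X), systematic full-coverage strip tiling, coordinate
    remapping of per-tile detections back to the full-resolution frame,
    cross-scale combination by Weighted Box Fusion or non-maximum
    suppression, and free-response ROC (FROC) evaluation under the
    center-in-box hit criterion standard in mammography CAD.  Includes a
    seeded generator of mammography-like phantoms with exact ground-truth
    boxes and a classical difference-of-Gaussians reference detector whose
    bounded sigma band emulates a fixed receptive field, so the
    resolution/scale/context behaviour of tiled multi-scale inference can
    be studied end-to-end without clinical data or a GPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
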