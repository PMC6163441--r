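Package: olivesizer
Title: Olive-Fruit Segmentation, Sizing and Mass Estimation from Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments olive fruits photographed on a bright conveyor mat and
    estimates their major/minor axis length and mass. The segmentation fuses
    the HSV saturation channel with the inverted value channel, removes the
    mat background by grayscale morphological opening, binarizes with Otsu's
    clustering threshold and cleans the mask by binary opening and
    reconstruction-based hole filling. Per-fruit descriptors (pixel area and
    ellipse axes from normalized second central moments) are calibrated
    against caliper/balance references with ordinary least squares, and both
    pixel-level segmentation scores (precision, recall, F-score) and model
    error metrics (RMSE, relative RMSE, relative mean error) are provided.
    A seeded synthetic conveyor-scene generator with exact ground truth makes
    the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jpeg,
    jsonlite,
    optparse,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
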