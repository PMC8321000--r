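Package: lungcad
Title: Automatic Lung Nodule Detection in Chest CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A fully automatic computer-aided detection (CAD) pipeline for
    pulmonary nodules in axial chest CT slices. Lungs are segmented per
    slice by histogram-based background removal (second-local-minimum
    threshold), Otsu separation and connected-component/morphological
    refinement. Bright inner structures are extracted from the parenchyma,
    round/near-round components are grown into candidate regions by seeded
    region growing, and each candidate is described by a six-element
    statistical feature vector including an across-slice consistency bit.
    A linear support vector machine separates nodules from vessels and
    bronchi. The package also provides the full detection-metric suite
    (sensitivity, specificity, precision, accuracy, F-beta, MCC, false
    positives per image and per exam), a minimal DICOM/PNG slice reader,
    and a seeded synthetic chest-phantom generator with ground truth so
    that every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
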