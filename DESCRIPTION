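Package: lattice123
Title: Dynamic Lattice Graph Pattern Feature Engineering for EEG Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Feature engineering and self-organized classification for multichannel
    EEG epochs built around a dynamic graph pattern on a fixed 19-vertex, 28-edge
    directed lattice. Each overlapping 19-sample block of a signal drives two greedy
    probability walks (minimum and maximum) through the lattice; signum and ternary
    comparison kernels along the walks yield 8-bit codes whose 256-bin histograms are
    textural feature vectors. Features are extracted at multiple scales via a
    four-level db4 discrete wavelet decomposition, selected with iterative
    neighborhood component analysis, classified with a city-block 1-nearest-neighbor
    under stratified cross-validation, and fused by iterative hard majority voting
    with greedy best-result selection at channel and record level. Includes a
    synthetic multichannel EEG generator with class-dependent spectral profiles,
    delimited-matrix and EDF readers, and a full metric suite (sensitivity,
    specificity, precision, F1, geometric mean) for imbalanced two-class problems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
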