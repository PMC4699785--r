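Package: nirsova
Title: One-vs-All Species Identification from Near-Infrared Spectra
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemometric identification of cryptic species from near-infrared
    reflectance spectra. Implements the one-vs-all reduction of a multi-class
    species problem to two-class calibrations, a NIPALS partial least squares
    regression core with pluggable random-forest and neural-network backends,
    population-atomic calibration/validation splitting at the nest level, a
    zero-false-positive exclusion-interval search with nestmate propagation,
    and the exhaustive-search cost calculus for three multi-class-reduction
    strategies. Includes a hierarchical synthetic-spectrum generator so the
    full routine is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    nnet,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    yaml
biocViews: Classification, Spectrometry, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
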