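Package: dmcvib
Title: Anharmonic Vibrational Spectra of Water Clusters from Diffusion
    Monte Carlo
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Samples nuclear ground-state wave functions of small
    hydrogen-bonded water clusters by guided diffusion Monte Carlo (DMC)
    on the flexible q-SPC/Fw point-charge surface and predicts anharmonic
    fundamental frequencies and infrared intensities from the sampled
    ground-state probability amplitude.  Provides continuous- and
    discrete-weighting DMC with importance sampling and descendant
    weighting, isomer search with Eckart alignment and permutation
    detection, redundant internal coordinates with Wilson B/G machinery,
    standard and chemically informed SVD redundancy reduction with
    character-imbalance diagnostics, and an optimization-based reverse
    mapping that turns abstract vibrational modes into Cartesian
    animations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
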