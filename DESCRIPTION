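Package: fireflash
Title: Trajectorization, Classification and Characterization of Firefly Flash Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated analysis of firefly bioluminescent flash
    patterns from 3D flash localizations recorded at 30 frames per second.
    Links flash detections into streaks and trajectories, extracts binary
    flash sequences, and classifies species with a gated recurrent unit
    (GRU) network trained by backpropagation through time, alongside four
    reference-based baselines (Jaccard index, dot product, dynamic time
    warping, and a radial-basis support vector machine). Includes stratified
    cross-validation with class-balancing undersampling, artificial-sympatry
    experiments, confidence-filtered population characterization of flash
    statistics, and a fully seeded synthetic swarm and sequence generator so
    every stage is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
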