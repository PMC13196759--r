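Package: photokin
Title: Light-Evoked Photokinesis Analysis for Cave and Surface Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for light-evoked locomotor (photokinetic)
    behavior in Astyanax mexicanus cave and surface morphs and their
    hybrids. Bins well-plate tracking data into fixed intervals, scores
    activity changes at light transitions with the photokinesis index,
    compares populations with Welch t-tests and Tukey-corrected one-way
    ANOVA, screens brain-region volumes against behavior with
    Benjamini-Hochberg control, clusters stimulus-tuned calcium traces
    by hierarchical clustering, and builds simplified voxelwise
    nonparametric activity maps with FDR thresholding. A synthetic-data
    generator emulates the full study design (alternating light/dark
    schedules, surface/cave/F1/F2 populations under an additive
    polygenic model, planted volume-behavior correlations, tuned
    fluorescence traces, and activation-blob phantoms) so every stage
    is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
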