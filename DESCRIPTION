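Package: lrescan
Title: Stem-Loop Binding Preference Modelling and LRE Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the RNA-binding specificity of stem-loop binding proteins
    such as LIN41/TRIM71 from RNAcompete-style in vitro selection data.
    Provides a thermodynamic RNA folding backend (minimum-free-energy
    structures and McCaskill base-pair probabilities, with ViennaRNA as an
    optional external engine), k-mer enrichment profiling of sequence versus
    secondary-structure preferences, two-channel array normalization with
    loess residual enrichments, a 2688-pattern tri-loop stem-loop binding
    model (LRE model), transcriptome-wide binding-site prediction with
    region and strength grading, linear regression of RIP enrichment on
    predicted-site features, and ligand-depletion binding isotherm fitting
    for fluorescence polarization data. Includes seeded synthetic-data
    generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    limma,
    minpack.lm,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
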