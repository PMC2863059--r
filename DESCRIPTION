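Package: foldrate
Title: Sequence-Based Protein Folding Kinetics Classification and Rate Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein folding kinetic type (two-state versus multi-state)
    and real-valued folding rates (log10 of k_f in 1/sec) from sequence-derived
    features: probability-weighted long-range contact order and contact number
    computed from predicted residue-residue contact probability maps, predicted
    secondary-structure composition, amino-acid composition and chain length.
    A radial-basis-kernel support vector classifier assigns the kinetic type and
    two kinetic-type-specific epsilon-support-vector regressors predict the rate,
    with strict leave-one-out cross-validation, grid-search hyperparameter tuning,
    repeated 90/10 split evaluation, single-feature screening and a linear
    regression baseline. Includes readers for FASTA, CASP-RR-style contact files,
    secondary-structure strings and PDB C-alpha coordinates, structure-derived
    contact descriptors, and a deterministic synthetic benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
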