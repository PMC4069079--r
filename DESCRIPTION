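Package: fvhotspots
Title: Structure-Based Prediction of Asparagine and Aspartate Degradation
    Hotspots in Antibody Variable Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts asparagine deamidation and aspartate isomerization
    hotspots in the variable (Fv) regions of monoclonal antibodies from
    ensembles of structure models. Extracts twenty structural descriptors
    (solvent accessibility, backbone and side-chain dihedrals, hydrogen
    bonds, secondary structure context, ensemble flexibility, CDR
    location), applies published decision-tree classifiers for Asp and Asn
    with an ensemble aggregation rule, provides a sequence-motif baseline
    scanner, and includes a retraining toolkit with class-weighted
    lookahead recursive partitioning and grouped Monte Carlo
    cross-validation. Synthetic peptide and descriptor-table generators
    support testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pracma,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
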