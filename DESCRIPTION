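Package: casforge
Title: Mining and Rational Engineering of Cas9 Proteins with a CNN-LSTM Sequence Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains a convolutional/recurrent (CNN-LSTM) classifier that
    separates Cas9-like protein sequences from composition-preserving
    partially shuffled negatives, extracts per-residue Grad-CAM saliency
    ("fingerprints") from the convolutional layer, runs a genome-mining
    filter cascade (length window, 100-residue bins, Pfam-domain bin
    selection, score thresholds, CRISPR-repeat ranking), and ranks candidate
    point mutations by combining a model-derived characteristic matrix with
    a position-specific amino-acid probability (PSAP) conservation matrix.
    Includes seeded synthetic-data generators (motif-planted positives,
    shuffled negatives, homolog families, toy mining tables) so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stringr,
    generics,
    withr,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
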