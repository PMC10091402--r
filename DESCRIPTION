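Package: rxnpredict
Title: Predictive Scenarios for Chemical Reaction Sequence Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and evaluating sequence-to-sequence
    predictive scenarios over chemical reactions: template-based synthetic
    reaction generation with realistic reactant/reagent count statistics,
    SMILES canonicalization and randomized (non-canonical) enumeration,
    SELFIES encoding and decoding, source-only data augmentation, atom-level
    and pair-encoding tokenization with frequency-thresholded vocabularies,
    skip-gram token embeddings, a compact encoder-decoder transformer with
    beam-search n-best inference and early stopping, and an evaluation suite
    covering strict and lenient top-k accuracy, round-trip accuracy against a
    matched forward model, molecule-level precision/recall/F1 at rank k,
    reagent-count binned analysis with weighted pooling, and two-group expert
    label agreement tabulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    jsonlite,
    withr
Config/testthat/edition: 3
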