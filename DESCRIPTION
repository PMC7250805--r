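Package: hmmann
Title: Dominant Protein Function Prediction from Profile HMM Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts the single dominant function of a protein sequence from
    its raw profile hidden Markov model (HMM) bit scores against a superset of
    candidate functions. Raw scores are expanded into pair-of-pairs (POP)
    combinatorial features, standardized, and summed into a per-sequence
    beta-value; per-function clusters of beta-values yield centroids,
    chi-squared refinement statistics and confidence intervals; a
    single-hidden-layer, single-output feed-forward neural network maps POP
    features to a scalar prediction that is assigned to the unique function
    whose interval contains it. Includes the combinatorial architecture table
    linking superset size to network size, HMMER3 tblout import, a seeded
    synthetic-score generator, and holdout/leave-one-out/empirical validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    nnet,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
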