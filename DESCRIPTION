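Package: spanfold
Title: Span-Constrained RNA Secondary Structure Ensembles at Genome Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact computation of RNA secondary-structure expected values
    (base-pairing and stem probabilities, accessibility, loop-type structural
    profiles, gamma-centroid structures) from the Boltzmann ensemble of
    globally consistent structures under a maximal base-pair span constraint.
    The inside-outside dynamic programme is carried out on position-to-position
    ratios of the exterior partition-function variables, so all stored
    quantities stay bounded in magnitude no matter how long the input sequence
    is, and the construction can be split into independent segment jobs and
    merged exactly (Divide/Connect). Also provides k-mer composition ridge
    regression for normalising windowed stem probabilities, evaluation metrics
    (MCC, ROC-AUC) and large-sample Wilcoxon rank statistics, plus an
    exhaustive-enumeration oracle for validation on short sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
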