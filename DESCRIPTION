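Package: rnamea
Title: Greedy Maximum Expected Accuracy Structural Alignment of Multiple
    RNA Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-progressive structural alignment of non-coding RNA
    sequences.  Posterior base-alignment probabilities from a pair hidden
    Markov model and base-pairing probabilities from a partition-function
    model are sharpened by inter-sequence, intra-sequence and four-way
    probabilistic consistency transformations; the multiple alignment is
    then assembled greedily as a directed acyclic graph of columns,
    starting from confident base-pairs (a structural skeleton) and
    continuing with confident base alignments, followed by a
    discriminative split-and-realign refinement.  Includes a synthetic
    RNA family simulator with compensatory mutations, alignment and
    structure evaluation metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
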