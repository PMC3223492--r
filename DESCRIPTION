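Package: alnbench
Title: Benchmarking Global and Local Pairwise Alignment Against Gold-Standard Evolutionary Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pairs of amino-acid sequences descending from a common
    ancestor under a Dayhoff PAM substitution model with Zipf-distributed
    insertions and deletions, flanks the homologous cores with random
    non-homologous terminal segments ("consoles"), and records the true
    (gold-standard) alignment implied by the simulation. Provides affine-gap
    optimal pairwise aligners (global Needleman-Wunsch/Gotoh and local
    Smith-Waterman/Gotoh), accuracy and confidence measures of algorithmic
    alignments against the gold standard, and an analytic alignment-density
    model that predicts the console asymmetry at which global alignment
    quality collapses ("slope zone"), together with drivers reproducing the
    full quality sweeps over evolutionary distance, console length and
    console asymmetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
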