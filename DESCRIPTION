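Package: codonSelect
Title: Codon Substitution Models and Tests for Positive Selection on
    Phylogenies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood fitting of codon substitution models
    (GY94-style) on unrooted phylogenies, with the branch, site, and
    branch-site model pairs used to detect positive selection in
    protein-coding genes: one-ratio (M0) versus two-ratio, nearly-neutral
    (M1a) versus positive-selection (M2a), and branch-site Model A null
    versus alternative. Nested models are compared by likelihood-ratio
    tests and positively selected sites are located by Naive and Bayes
    Empirical Bayes posteriors. Includes mitochondrial genetic codes, a
    codon-alignment simulator for power and calibration studies, and a
    per-gene multi-foreground analysis pipeline producing machine-readable
    selection reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    ape,
    Biostrings,
    Rcpp,
    yaml,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Phylogenetics, SequenceAnalysis, Genetics, Software
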