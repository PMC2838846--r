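Package: kinomeprofiler
Title: Kinome Identification, Classification and Comparative Analysis from
    Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative protein kinases in a proteome by profile
    hidden Markov model bit score, classifies them into the twelve canonical
    kinase groups with a fixed-cutoff, maximum-score rule, annotates flanking
    protein domains and partitions them into catalytic versus accessory, and
    compares species cohorts by group counts, normalized frequencies, kinome
    density (Wilcoxon rank-sum) and prevalence-filtered domain-frequency
    principal component analysis. Ships a synthetic-cohort generator with
    full ground truth and a command-line entry point for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
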