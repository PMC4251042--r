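Package: foldrec
Title: Protein Fold Recognition by Random-Forest Template Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for template-based protein fold
    recognition. Every ordered (target, template) pair of proteins is
    described by pairwise similarity features (amino-acid composition
    kernels, sequence-sequence, sequence-profile and profile-profile
    alignment scores, and secondary-structure/accessibility compatibility),
    classified by a from-scratch random forest with per-class probability
    output, and templates are ranked per target.  Recognition sensitivity is
    scored at the family, superfamily and fold levels of the SCOP hierarchy
    under the Lindahl top-1/top-5 protocol, with grouped cross-validation,
    template-leakage removal and negative-class subsampling.  A synthetic
    benchmark generator produces Lindahl-like datasets with a controlled
    fold/superfamily/family hierarchy so the whole pipeline can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    readr,
    ggplot2,
    withr,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest
Config/testthat/edition: 3
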