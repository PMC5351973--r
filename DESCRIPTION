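Package: gwsel
Title: Genomic-Wide Selection for Small Perennial-Crop Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic-wide selection (GWS) in small breeding
    populations typical of perennial crops such as Jatropha curcas.
    Provides a synthetic-data generator for half-sib germplasm and diallel
    full-sib designs with known genetic architecture; EM-REML variance
    components and genetic parameters (heritability, coefficients of
    variation) for block-design mixed models; a VanRaden genomic
    relationship matrix, identity-by-state distances and classical
    multidimensional scaling for diversity analysis; eight whole-genome
    regression models (RR-BLUP, G-BLUP, Bayesian ridge regression, Bayes A,
    Bayes B, Bayes C-pi, Bayesian LASSO and Gaussian-kernel RKHS) with a
    compiled Gibbs sampler; k-fold cross-validated prediction ability; and
    a marker-density backward-elimination study producing prediction-ability
    and heritability curves as a function of marker number.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
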