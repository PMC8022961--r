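Package: qtlx
Title: Multiple-QTL Model Selection with X-Chromosome-Aware Penalties
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Penalized-LOD stepwise model selection for quantitative trait
    loci (QTL) in experimental crosses (backcross and F2 intercross) that
    treats the X chromosome correctly: sex and cross-direction covariates in
    the null model, X-specific design columns, separate main-effect penalties
    for autosomes and the X chromosome, and separate epistasis penalties for
    autosome-autosome, autosome-X and X-X interactions.  Includes Haley-Knott
    regression genome scans (single-QTL and two-dimensional two-QTL), hidden
    Markov model genotype probabilities, a cross simulator with a mouse-like
    genome, Monte-Carlo derivation of all penalty classes from null scans,
    and reading/writing of CSV cross files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
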