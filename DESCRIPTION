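Package: dctnet
Title: Dynamic Cross-Tissue Network Analysis of Paired Multi-Tissue Transcriptomes
Version: 0.1.0
Authors@R:
    person("DCT", "Maintainers", email = "maintainers@dctnet.example.org", role = c("aut", "cre"))
Description: Integrates paired case/control expression matrices measured over the
    same tissues and genes using a joint-correlation non-negative matrix
    factorization (jcNMF) that softly constrains the two tissue-loading matrices
    to share a conserved tissue-correlation structure (W1 W1' = W2 W2' = R).
    From the fitted factors it builds per-tissue Pearson co-expression networks,
    derives differential networks (edges specific to one condition), ranks genes
    by their mean correlation with a set of known phenotype-anchor genes, forms
    cross-tissue consensus candidates, and identifies the key tissue by a
    matched-pair t-test on differential network degrees. A synthetic paired-data
    generator with planted modules, planted condition-specific edges and planted
    anchor-correlated genes supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
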