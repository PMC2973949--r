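Package: sparselap
Title: Sparse Laplacian Eigenfunctions for Population Structure and
    Ancestry-Informative Marker Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Summarizes population structure from genome-wide SNP genotypes
    by embedding individuals with the eigenfunctions of a normalized graph
    Laplacian built on an epsilon-neighborhood Gaussian kernel graph, and
    selects small panels of structure-informative (ancestry-informative)
    markers by fitting sparse elastic-net loadings of the markers on the top
    eigenfunctions.  Includes a stepping-stone ring-population coalescent
    simulator with isolated outlier demes, a Balding-Nichols discrete
    population generator, a whole-genome stepwise scan for very large marker
    sets, a PCA-based marker-selection comparator with QR redundancy
    pruning, and evaluation tools: Mantel permutation tests, eigenmap
    correlations, pairwise LD r-squared panel summaries, SVM membership
    prediction, and Rosenberg's informativeness for assignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    e1071,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
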