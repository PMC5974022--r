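Package: fmnet
Title: Functional Metagenomic Networks from Amplicon and NMR Metabolomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated microbiome-metabolome analysis toolkit for
    cirrhosis-style cohort studies. Provides 16S amplicon abundance
    preprocessing (rarefaction, relative abundance, prevalence filtering,
    alpha and beta diversity, principal coordinate ordination), 1D NMR
    spectral preprocessing (rolling-ball baseline removal, spectral
    alignment, fixed-width bucketing, total-integral and probabilistic
    quotient normalization), construction of thresholded signed Pearson
    co-occurrence networks over merged taxon and metabolite features with
    Louvain community detection and betweenness-centrality keystone
    ranking, feature-to-clinical cross-correlation with
    Benjamini-Hochberg false discovery rate control, and a consensus
    hepatic-encephalopathy risk ranking combining univariate logistic
    regression (with base-2 odds ratios), stability-selection randomized
    lasso, elastic net, and a stochastic-gradient-descent classifier.
    Includes a synthetic cohort generator with planted correlation-block
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    vegan,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
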