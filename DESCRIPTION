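Package: raretide
Title: Co-Abundance Gene Groups and Seasonality of Rare and Abundant
    Marine Metagenomic Gene Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising the rare (unassembled) versus
    abundant (assembled) gene pools of marine metagenomic time series
    from feature-by-sample abundance tables.  Implements prevalence and
    singleton filtering, Bayesian-multiplicative zero replacement and
    centred log-ratio transformation, Dirichlet Monte-Carlo
    compositional differential abundance between read fractions,
    binning of Co-Abundance gene Groups (CAGs) by partial least squares
    relevance networks and by canopy clustering, signed Spearman
    CAG-environment networks with Louvain clusters and
    expected-influence keystone ranking, Bray-Curtis lag-similarity
    seasonality analysis with ANOSIM, and KEGG-ortholog pathway
    coverage summaries.  A synthetic time-series generator emulating
    the statistical structure of a monthly coastal metagenomic survey
    supports end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    mclust,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
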