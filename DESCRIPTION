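Package: denitnet
Title: Compositional, Network and Machine-Learning Analysis of Soil
    Denitrification Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline linking soil microbial community structure
    to the controls of nitrous oxide emissions. Partitions OTUs into
    frequent and rare fractions with an index-of-dispersion test on mean
    rarefied abundances; applies Bayesian-multiplicative zero replacement,
    the centred log-ratio transform and the phylogenetic isometric
    log-ratio (balance) transform; tests per-balance fertilization effects
    with site-random-intercept mixed models and false discovery rate
    control; builds treatment-wise Pearson co-association networks
    thresholded by random matrix theory (nearest-neighbour eigenvalue
    spacing), with topology metrics, Erdos-Renyi null tests,
    edge-betweenness module detection and module eigengene analysis;
    compares networks by shared and unique edges and per-node rewiring
    scores; models denitrification end-product ratios with tuned boosted
    regression trees, permutation variable importance and accumulated
    local effects; and estimates potential denitrification and N2O
    production rates from gas accumulation time series. A synthetic-study
    generator with recorded ground truth supports recovery testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    vegan,
    permute,
    picante,
    igraph,
    lme4,
    lmerTest,
    minpack.lm,
    xgboost,
    jsonlite
Suggests:
    pbkrtest,
    biomformat,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
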