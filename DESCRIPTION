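Package: tillagebbn
Title: Bayesian Belief Network Analysis of Tillage Choice for Winter Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete Bayesian belief network (BBN) engine and an
    agro-ecosystem case study comparing no-till and conventional tillage
    for winter wheat. Provides network construction and validation,
    conditional-probability-table learning from complete seasonal case
    data with a Dirichlet pseudo-count prior, exact posterior inference
    by variable elimination, quantile discretization of continuous
    variables into ordered bands, chronological holdout and decade-block
    K-fold validation with confusion matrices and proper scoring rules
    (logarithmic, quadratic/Brier, spherical), sensitivity-to-findings
    analysis (variance reduction, mutual information, variance of
    beliefs), scenario influence reports, and a seeded stochastic
    generator emulating crop-soil-climate simulation output so the whole
    pipeline is reproducible without external simulators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), igraph, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
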