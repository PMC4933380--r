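Package: netinflux
Title: Dynamical Influence of Rate Constants and Protein Domains in
    Biochemical Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the dynamical influence of reaction rate constants in
    ordinary-differential-equation models of biochemical networks: a
    normalized, time-integrated first-order sensitivity of every molecular
    species' trajectory to each rate constant, summed over stimulation
    conditions, and aggregated to protein domains by geometric averaging.
    Includes forward-sensitivity and finite-perturbation engines built on
    deSolve, model-derived covariates (protein abundance, domain-graph degree
    and betweenness centrality), per-network Spearman, rank-biserial and
    partial correlations, Hunter-Schmidt random-effects meta-analysis of
    correlations across networks, structured permutation tests, between-model
    overlap correlations with an overlapping-domain randomization, and a
    synthetic-data generator producing mass-action signaling cascades and
    multi-network domain populations with planted rank-correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
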