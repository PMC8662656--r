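Package: bathypop
Title: Habitat-Linked Population Divergence and Larval Connectivity of a
    Deep-Sea Limpet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for habitat-linked population divergence
    of deep-sea vent and seep invertebrates, exercised on synthetic data.
    Provides a coalescent simulator for competing founder-bottleneck
    demographic scenarios, a genotyping-by-sequencing SNP filtering
    cascade, population-genetic statistics (Weir-Cockerham F_ST with
    permutation tests, per-group diversity, Nei distance, genotype PCA),
    directional relative migration from the migrant-pool G_ST method,
    approximate Bayesian computation for scenario choice and demographic
    parameter estimation, and Lagrangian ocean-particle release
    experiments on synthetic trough/boundary-current velocity fields with
    bathymetric constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    nnet,
    geosphere,
    jsonlite,
    digest,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
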