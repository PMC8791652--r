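Package: lipidmets
Title: Consensus Lipidomics-Metabolomics Analysis of Metabolic Syndrome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for case-control plasma lipidomics with
    metabolomics and clinical integration, built for studies of metabolic
    syndrome in treated HIV cohorts. Parses complex-lipid-panel shorthand
    nomenclature into structural lipid identities; preprocesses concentration
    matrices (minimum imputation, median centering, near-zero-variance
    filtering, log transform); selects differentially abundant lipids by
    consensus across four methods (Mann-Whitney U, empirical-Bayes moderated t,
    PLS-DA variable importance, and repeated double cross-validated random
    forest); summarises group effects over carbon-number by double-bond
    structural grids; and integrates lipids with key metabolites in a weighted
    positive-Spearman network with an Erdos-Renyi null, Leiden communities,
    degree hubs, community-clinical regression and hypergeometric
    over-representation analysis. Ships a synthetic cohort generator with
    ground-truth effect labels so the full pipeline is testable without access
    to the original cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mixOmics,
    caret,
    mclust,
    pROC
Config/testthat/edition: 3
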