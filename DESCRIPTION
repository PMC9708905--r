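Package: sysphar
Title: Systems Pharmacology Analysis of Concentration-Dependent Multi-Omics
    Perturbations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mode-of-action analysis of a compound from
    multi-omics dose-response data. Fits per-feature linear
    concentration-response models with Benjamini-Hochberg control, runs
    weighted Kolmogorov-Smirnov gene set enrichment on t-statistic-ranked
    genes, matches differential signatures against a perturbagen library by
    Spearman connectivity with an empirical permutation null, compares small
    molecules by hashed path/sphere and dictionary fragment fingerprints with
    Tanimoto similarity, and infers a parsimonious signed causal subnetwork
    from a perturbation to inferred transcription factor activities by integer
    linear programming over a prior knowledge network. Ships a synthetic-data
    generator with planted ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
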