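Package: phaseomics
Title: Differential Abundance and Cross-Phase Proteome Prediction for
    Two-Strain Multi-Omics Designs
Version: 0.1.0
Authors@R:
    person("phaseomics", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for small-n two-strain multi-omics studies: readers and
    normalizers for targeted-metabolomics and label-free proteomics
    abundance tables (internal-standard and wet-weight normalization,
    MaxQuant proteinGroups import), per-feature differential abundance
    (Student t-tests, Storey q-values, fold-change/p-value gating,
    presence-absence screening), PCA with pathway-annotated biplots, a
    classical regression benchmark (PLS, ridge, lasso, random forest,
    gradient-boosted trees) under leave-one-out cross-validation, a
    pathway-graph attention network that predicts later-growth-phase
    protein abundance from earlier multi-omics profiles, fold-change
    concordance reporting, and a seeded synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
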