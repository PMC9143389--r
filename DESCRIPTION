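Package: skinperm
Title: Two-QSAR Modelling of Skin Permeability Coefficients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates quantitative structure-activity
    relationship (QSAR) models of the skin permeability coefficient
    (log10 Kp, cm/h) with a two-model scheme: a predictive hierarchical
    support vector regression (HSVR) -- an ensemble of RBF-kernel SVR
    members with distinct descriptor subsets stacked under a meta-SVR --
    alongside an interpretable partial least squares (PLS) regression.
    Includes descriptor-table ingestion, missing/invariant/collinearity
    filtering with Spearman rank pruning, autoscaling, ion-class
    assignment from pKa, PCA chemical-space projection with
    diversity-preserving train/test splitting, genetic-algorithm and
    recursive-feature-elimination descriptor selection, and the full
    external-validation statistic battery (qF1-qF3, concordance
    correlation coefficient, the rm2 family, through-origin regression
    diagnostics, stringent acceptance criteria, 10-fold cross-validation,
    and Y-scrambling), plus a seeded synthetic-data generator emulating
    the statistical structure of curated skin-permeation datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
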