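Package: lipidMAE
Title: Factorial-Design Optimization and Chemometric Screening for
    Microwave-Assisted Lipid Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing Microwave-Assisted Extraction (MAE) of
    lipids from dairy matrices and for downstream lipidomic data analysis.
    Implements two-level full factorial designs with center replicates,
    per-subclass 8-term factorial response models with coefficient
    inference, multivariate screening diagnostics (PCA, average-linkage
    hierarchical clustering on squared Euclidean distances, and PLS-DA
    validated by double cross-validation and bootstrap with Q2/DQ2
    statistics), Pareto-front multi-objective optimization on
    principal-component response surfaces, and a lipid shorthand
    nomenclature parser with fatty-acyl characterization, inventory
    summaries, method comparison and QC gating. A deterministic
    synthetic-data generator emulates the abundance tables, solvent
    screening structure and identification exports the workflow consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
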