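Package: edsig
Title: Discovery and Scoring of Blood Cell Gene-Expression Signatures in
    Pulmonary Hypertension Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for discovering correlated
    gene-expression signatures in peripheral blood mononuclear cell (PBMC)
    microarray cohorts and relating them to clinical severity of pulmonary
    hypertension. Implements per-sample median scaling and detection-p-value
    filtering of bead-array intensities, detection-gated Welch-t /
    Benjamini-Hochberg / fold-change differential expression, hierarchical
    clustering with uncentered correlation, expansion of seed clusters into
    full signatures by correlation with the cluster centroid (the erythroid
    development signature, EDS, procedure), parametric gene-set enrichment
    (PAGE) in group-contrast and per-sample landscape variants, scoring of a
    signature in external expression datasets, correlation of surrogate
    biomarkers with hemodynamic measurements, and a seeded synthetic-cohort
    generator that emulates the statistical structure of a five-group
    PBMC study for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
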