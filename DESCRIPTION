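Package: ehrkit
Title: Exploratory Analysis of Electronic Health Record Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An annotated observations-by-variables container for mixed-type
    patient-visit tables, with quality control (missingness metrics, Little's
    MCAR test, winsorization, clipping, bias detection), categorical encoding,
    imputation (explicit, simple statistics, k-nearest neighbours, iterative
    random forests), normalization with optional group-wise fitting, PCA /
    neighbour-graph / UMAP / Leiden patient stratification, group feature
    ranking (t-test and g-test with Benjamini-Hochberg correction), survival
    statistics (Kaplan-Meier, log-rank, Cox models, bootstrapped concordance),
    backdoor-adjusted causal effect estimation with refutation checks, cohort
    filtering provenance, and a synthetic cohort generator so every stage can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    uwot,
    ranger,
    RANN,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
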