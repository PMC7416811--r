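Package: riskclust
Title: Biomarker Risk-Profile Consensus Clustering for Survival Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised stratification of palliative oncology cohorts from
    survival-linked biomarker panels. Fits a confounder-adjusted Cox
    proportional-hazards model independently for each biomarker (Newton-Raphson
    partial-likelihood maximisation with Efron tie handling, stepwise selection
    by the Akaike Information Criterion, Grambsch-Therneau proportional-hazards
    diagnostics), concatenates the per-model linear predictors into a
    patient-level risk profile, clusters the profiles by resampling-based
    consensus hierarchical clustering with delta-area selection of the number
    of clusters, and characterises the resulting clusters (Kaplan-Meier curves
    and the log-rank test, confounder-association tests, pairwise Wilcoxon
    rank tests with Benjamini-Hochberg correction, min-max normalised biomarker
    patterns and subgroup summaries). A seeded synthetic-cohort generator with
    planted subgroups, subgroup-shifted biomarkers and biomarker-dependent
    proportional hazards makes the whole pipeline testable without access to
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
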