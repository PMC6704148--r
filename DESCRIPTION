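Package: sigcordance
Title: Cross-Comparison of Breast Cancer Multigene Signatures in Clinical Assessment Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-comparing multigene expression signatures in
    population-based breast cancer cohorts. Provides a seeded synthetic
    cohort generator with latent molecular subtypes, correlated expression
    axes and proportional-hazards survival; a configurable classification
    engine covering nearest-centroid subtype predictors, weighted-module
    risk scores, risk-of-recurrence (ROR) variants and correlation-to-template
    risk calls; stratification of patients into nine adjuvant clinical
    assessment groups from immunohistochemistry, nodal status and treatment
    flags; pairwise exact-agreement statistics, Bangdiwala-style agreement
    chart geometry and consensus risk voting; and Kaplan-Meier, log-rank and
    Cox proportional-hazards outcome analysis per signature class within
    assessment groups, including a configurable small-class exclusion rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
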