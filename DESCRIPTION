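Package: dtpd
Title: Concept-Mapping Development and Validation Analytics for a Clinical
    Referral Decision Tool
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the complete statistical pipeline by which a
    seven-criterion clinical referral decision tool for personality
    disorders (DTPD) is developed from group concept mapping and validated
    on a multi-centre patient cohort. Covers card-sort co-occurrence
    similarity matrices, nonmetric multidimensional scaling with Kruskal
    stress-1, hierarchical (Ward) cluster ladders, bridging values, rating
    summaries with Bonferroni-corrected pairwise tests, sorter reliability
    with Spearman-Brown correction, the sum-score-plus-gate scoring rule,
    marginal logistic regression with exchangeable working correlation for
    clustered binary outcomes, ROC/AUC with DeLong intervals, cut-off
    sensitivity/specificity tables, Cronbach's alpha, and seeded synthetic
    generators for sorting studies, rating tasks and multi-centre cohorts.
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
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
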