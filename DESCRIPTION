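Package: lnstage
Title: Comparing Lymph Node Classification Systems for Survival
    Discrimination in Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing nodal staging systems (AJCC/UICC N
    category, lymph node ratio, and log odds of positive lymph nodes)
    with respect to overall-survival discrimination in radically
    resected, non-metastatic colorectal cancer. Provides per-patient
    nodal metrics, a registry of published interval-based LNR/LODDS
    classifications, covariate-adjusted Cox proportional-hazards
    modelling, Harrell's concordance index with jackknife inference on
    paired C-statistic differences, Benjamini-Hochberg false discovery
    rate control, landmark ROC analysis for censored survival, a seeded
    synthetic cohort generator calibrated to published summary tables,
    and an end-to-end analysis pipeline with subgroup support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
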