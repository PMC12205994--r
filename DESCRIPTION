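Package: her2strat
Title: HER2 mRNA Stratification of Breast Cancer Subgroups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives HER2 expression cutoffs from microarray intensities by
    receiver operating characteristic (ROC) analysis against IHC/FISH-defined
    HER2 status, stratifies breast-cancer cohorts into six hormone-receptor by
    HER2 subgroups (HER2-positive, HER2-low, HER2-ultralow crossed with HR+/-),
    compares relapse-free, distant-metastasis-free and overall survival between
    subgroups with Kaplan-Meier curves and log-rank tests, and scores immune
    gene-signature activation per subgroup with a dual rank-sum P and AUC
    criterion. Ships a synthetic-cohort generator with planted expression
    boundaries, class proportions, subgroup hazards and signature effects so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
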