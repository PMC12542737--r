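Package: drugmem
Title: Active, Carryover and Additive Drug Effects on the Gut Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects active, long-term carryover and cumulative (additive)
    effects of medications on the gut microbiome from ATC-coded prescription
    histories linked to shotgun-metagenomic taxon profiles. Classifies
    per-subject drug exposure (active, former with years since last use,
    never) from registry records, applies compositional data analysis
    (centered log-ratio transform, Aitchison distances), fits
    covariate-adjusted abundance and presence-absence association models with
    Benjamini-Hochberg control, scans multi-year carryover windows, selects
    among competing additive-effect models by AIC, assigns nested-model
    deconfounding statuses, validates effects across two sampling time
    points, partitions community variance by distance-based redundancy
    analysis, and evaluates the transfer of antibiotic-usage classifiers to
    other drug classes. A seeded synthetic-cohort generator with planted
    effects makes every stage testable without access-restricted data.
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
    glmnet,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
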