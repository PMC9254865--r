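Package: psmcea
Title: Partitioned Survival Cost-Utility Modelling for First-Line Therapy in
    Advanced Renal Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A partitioned survival (PFS/OS) cost-utility model for comparing
    first-line lenvatinib plus pembrolizumab and lenvatinib plus everolimus
    against sunitinib in advanced renal cell carcinoma from a Chinese health
    system perspective. Provides a synthetic trial-data generator calibrated
    to published medians and hazard ratios, reconstruction of pseudo
    individual patient data from digitized Kaplan-Meier curves and
    number-at-risk tables, maximum-likelihood fitting of six parametric
    survival families with AIC/BIC selection, a discounted three-state
    occupancy engine with mid-cycle correction, costing and utility valuation,
    and incremental, one-way, probabilistic (CEAC), scenario and subgroup
    decision analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
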