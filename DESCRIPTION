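Package: folfirisim
Title: Tumor-Microenvironment Dynamics Under FOLFIRI Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven ordinary-differential-equation model of the colon-cancer
    tumor microenvironment (T-cells, dendritic cells, macrophages, cancer and
    necrotic cells, and key cytokines) coupled to the pharmacodynamics of the
    FOLFIRI regimen (5-fluorouracil, leucovorin, irinotecan). Provides
    steady-state parameter derivation in the dimensionless scale, clinically
    shaped infusion schedules, stiff integration of the treated and untreated
    systems, combination / start-time / dose / parameter scans, time-dependent
    forward sensitivity analysis with parameter ranking, synthetic patient-cohort
    generation, and ROC-based validation of tumor-status predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
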