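Package: drscore
Title: Diabetes Remission Score for Ileal Interposition Metabolic Surgery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the seven-component Diabetes Remission Score (DRS) used
    to predict remission of type 2 diabetes after ileal interposition with
    sleeve gastrectomy (IISG) or with diverted sleeve gastrectomy (IIDSG).
    Provides the study eligibility and remission rules, per-procedure
    remission-probability bands with a procedure recommendation, two-sample
    t-tests computable from printed summary statistics, a calibrated synthetic
    cohort generator, and an exhaustive solver that reconstructs feasible
    per-score patient counts from published aggregate statistics.
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
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
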