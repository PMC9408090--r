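Package: wpaicost
Title: Health-Related Work Productivity Loss Costing for FIFO Workforces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores health-risk instruments (K10, SF-8 PCS, AUDIT-C, IPAQ,
    sleep, diet, smoking, BMI) into high/low risk flags, computes WPAI-GH
    absenteeism, presenteeism and total productivity loss under a 4-week
    recall, attributes excess losses to health conditions as annual
    human-capital costs per worker and per 1000 workers (unadjusted group
    differences and covariate-adjusted regression coefficients), fits
    two-part (hurdle) predictor models, and propagates parameter
    uncertainty with Monte-Carlo probabilistic sensitivity analysis.
    Includes a calibrated synthetic cohort generator emulating a fly-in
    fly-out mining workforce so the whole pipeline is testable without
    access to survey microdata.
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
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
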