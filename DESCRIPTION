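Package: oncoclaims
Title: Treatment Patterns and Healthcare Resource Use from Oncology Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal administrative claims from
    oncology cohorts: eligibility screening with washout rules, claims-based
    inference of metastatic versus early-stage disease, construction of lines
    of therapy from drug claims using switch and gap rules, classification of
    neoadjuvant and adjuvant treatment settings, and per-patient-per-month
    (PPPM) estimation of healthcare resource utilization and costs with exact
    Poisson and moment-matched gamma confidence intervals. Includes a
    synthetic claims generator with exported ground truth so every stage of
    the pipeline can be validated without access to proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    tibble,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
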