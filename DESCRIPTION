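Package: hairmetric
Title: Hemorrhage-Adjusted Iron Requirements from Quantified Blood Losses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the hemorrhage-adjusted iron requirement (HAIR), a daily
    dietary iron target that adds, to the national reference intake, the iron
    needed to replace quantified non-menstrual blood losses averaged over a
    three-month window. Includes conversion of epistaxis severity-score
    tick-box answers into monthly nosebleed blood volumes, calibration of
    bleed rates (mL/min percentiles) from timed-bleed survey records with
    unit conversion and outlier exclusion, dietary shortfall assessment
    against reference-intake schemes, cohort-level validation analyses
    (natural-breaks quintiles, quadratic regressions of hematinic indices on
    HAIR, nonparametric comparisons, stepwise logistic models), a quadratic
    hepcidin-ferritin regulatory model with hepcidin:ferritin ratio
    statistics, and a deterministic synthetic-cohort generator for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
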