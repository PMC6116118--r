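Package: breakfastcmr
Title: Breakfast Quality, Energy Density and Cardiometabolic Risk in Children
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores breakfast adequacy from 24-hour dietary recalls using a
    10-item Breakfast Quality Index (BQI) and breakfast energy density
    computed separately for solid foods (BEDs) and energy-containing
    beverages (BEDb); derives cardiometabolic outcome variables (HOMA
    insulin resistance, IDF-style pediatric metabolic syndrome
    classification and continuous z-score, center-standardized adiposity);
    and estimates exposure-outcome associations through a three-model
    covariate-adjustment ladder with stratified, sex-interaction and
    puberty sensitivity analyses. A synthetic two-center cohort generator
    with a packaged breakfast food library makes the full pipeline testable
    without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
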