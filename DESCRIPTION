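Package: dietvalidr
Title: Validation of Dietary Assessment Methods Against Doubly Labelled
    Water and Repeated 24-h Recalls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating self-reported dietary intake in cohort
    studies. Aggregates per-item 24-h dietary recall records into daily and
    per-participant energy, macronutrient and food-group intakes with
    energy-based plausibility screening; scores diets against food-based
    dietary guidelines with the nine-component Swedish Healthy Eating Index
    (SHEI); computes total energy expenditure from doubly labelled water
    (DLW) isotope-elimination series via the two-pool Speakman equation and
    a food-quotient energy equivalent of CO2; and compares paired
    measurement methods with Bland-Altman limits of agreement,
    difference-on-average regression, paired location tests and
    correlations. A calibrated synthetic-cohort generator with stored
    ground truth makes the entire pipeline testable without access to
    participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
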