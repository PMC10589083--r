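Package: nutriprod
Title: Economic and Nutrient Productivity of Integrated Aquaculture-Agriculture Farming Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supply-side metrics for nutrition-sensitive agriculture from farm
    household survey microdata. Classifies aquaculture farms into a 4 x 4
    farming-system typology (aquatic species combination by terrestrial
    integration), computes economic productivity (US$ per hectare, gross
    margin with self-consumption valued at sale prices) and nutrient
    productivity (annual adult equivalents per hectare for energy, protein,
    calcium, iron, zinc, vitamin A and vitamin B12, normalized by adult
    recommended dietary allowances), and runs fixed-effects ordinary
    least-squares regressions of both outcomes on food-group yields. Includes
    a structural synthetic-survey generator with known ground truth for
    end-to-end and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    lmtest,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
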