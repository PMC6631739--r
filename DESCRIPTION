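Package: sbmetrics
Title: Stillbirth Rates, Stillbirths-Adjusted Life Expectancy, and Years of Life Lost
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Consistent stillbirth-rate definitions with exact interconversion
    between the live-birth-denominated rate (SLBR, the ICD "fetal death ratio")
    and the total-birth-denominated rate (STBR, the "fetal death rate");
    stillbirths-adjusted life expectancy (SALE) and the implied life-expectancy
    decrement; stillbirth DALY/YLL in person-years; two-point growth
    decomposition linking changes in SLBR, NMR and their ratio; regional and
    income-group aggregation (pooled rates, cross-country dispersion, YLL
    totals, between-group gaps); delimited-text panel I/O with row-level
    validation; a seeded synthetic panel generator for property testing; and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
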