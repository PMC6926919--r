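Package: radonrisk
Title: Radon Progeny Exposure Assessment and Lifetime Lung-Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing population exposure to radon progeny and the
    associated lifetime risk of lung cancer. Aggregates regional indoor radon
    surveys into population-weighted national means by building class, converts
    radon gas concentrations to equilibrium-equivalent progeny concentrations
    via equilibrium factors, combines them with age-specific time-activity
    patterns into annual and lifetime exposure histories in working level
    months (WLM), and evaluates an excess-relative-risk model with
    time-since-exposure windows and an attained-age modifier through a
    BEIR-IV-style life table to obtain lifetime absolute risk, baseline risk,
    relative risk, and per-location attribution of the excess risk. Includes a
    synthetic-data generator for survey tables and sex-specific mortality
    tables, and a Monte-Carlo cohort simulator that serves as an independent
    check on the analytic life-table engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
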