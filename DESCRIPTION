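Package: importcost
Title: Import Cost Measurement and Accounting for Medical Supply Shipments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures and accounts the import costs (air freight, land
    freight, and customs clearance) of medical supply shipments using
    activity-based cost allocation. Transport costs are split across
    shipment parts and cargo types in proportion to gross weight, allocated
    to individual units via per-kilogram net-weight rates, and customs agent
    fees are allocated per customs item line. Includes missing unit-weight
    imputation by ingredient substitution and packaging-group medians,
    import-cost-contributor classification, a golden fixture encoding the
    aggregates of a 2016 tuberculosis-program shipment to Karakalpakstan,
    Uzbekistan, a seeded synthetic shipment generator, a CSV/YAML ingestion
    and reporting pipeline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
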