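Package: lifecost
Title: Extinction Opportunity Costs of Food Production and Consumption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a marginal-extinction-risk land layer (a LIFE-style
    "restore" raster, expected extinctions per km2 forgone by continued
    agricultural land use) with gridded crop production, livestock
    distributions and country-level supply and trade accounts to estimate
    the opportunity cost to biodiversity of producing or consuming one
    kilogram of each food commodity in each country. Includes
    production-mass-weighted quantile aggregation, feed and grazing
    attribution for animal products, a re-export (provenance) correction
    for bilateral trade, per-capita consumption footprints with
    import/domestic decomposition, and calorie-conserving diet-scenario
    comparisons. A seeded synthetic-world generator emulates the spatial
    and accounting structure of the real datasets so the full pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
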