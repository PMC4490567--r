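Package: oceanfootprint
Title: Marine Food Footprint, Sourcing Distance and Seafood Supply Limits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the human footprint on ocean primary
    production through seafood extraction and trade. Computes primary
    production required (PPR) from gridded catch records and taxon trophic
    levels, maps PPR/PP exploitation ratios into area bands, estimates the
    fraction of accessible (<1,000 m) ocean productivity appropriated by
    fishing with Monte Carlo uncertainty, estimates yearly catch-weighted
    median minimum seafood-sourcing distances with hierarchical bootstrap
    confidence limits, models the joint wild-capture plus fishmeal-limited
    mariculture supply ceiling, and projects seafood demand to 2100 under
    population scenarios. A fully seeded synthetic-world generator (grid,
    productivity fields, EEZs, ports, catches, trade, mariculture,
    population) supplies all inputs so the complete pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
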