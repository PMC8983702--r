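Package: hdfingerprint
Title: Hotter-Drought Fingerprint Analysis of Tree-Mortality Events
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the joint climate signal ("hotter-drought
    fingerprint") associated with documented tree-mortality events. Reads
    and validates geo-referenced mortality plot tables, deduplicates plots
    to 1/24-degree climate-grid cells, classifies Whittaker biomes,
    computes monthly climatologies and oriented standardized anomalies
    (z-scores) of six climate variables around mortality onset, composites
    them into global and per-biome fingerprints, tallies concurrent
    six-variable exceedances, and estimates the frequency of
    mortality-year threshold conditions under pattern-scaled warming
    scenarios. Includes a fully seeded synthetic-data generator so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
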