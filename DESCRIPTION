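Package: gillnetr
Title: Quantifying Illegal Gillnet Fisheries and Their Capacity to
    Overexploit Fish Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for characterizing an illegal gillnet
    fishery from indirect and direct evidence: derelict-fishing-gear
    transect surveys (linear densities, mesh composition, between-year
    re-accumulation), multi-mesh gillnet monitoring (length-weight
    allometry, panel- and set-level catch per unit effort, optimal mesh,
    mixed-model abundance and body-size trends with site random
    intercepts), and a data-poor stock assessment chain (von Bertalanffy
    growth, length-converted catch curve total mortality,
    life-history-invariant natural mortality, F at maximum sustainable
    yield, sustainable yield, and the fishing-effort scenarios required
    to reach it). Includes synthetic-data generators with the
    statistical structure the analyses assume, so every stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    lme4,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
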