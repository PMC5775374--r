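Package: hazscreen
Title: Exposure-Based Screening-Level Prioritization of Organic Chemicals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening-level prioritization of organic chemicals for four
    exposure-based hazard profiles: persistent organic pollutant (POP), very
    persistent and very bioaccumulative (vPvB), airborne persistent
    contaminant (APC) and waterborne persistent contaminant (WPC). Implements
    an evaluative three-compartment multimedia fate model that converts
    partition ratios and degradation half-lives into overall persistence
    (Pov), characteristic travel distances in air and water (CTD) and
    atmospheric transfer efficiency (TE); a single-fish steady-state
    bioaccumulation factor (BAF) model; data curation (ionizability
    exclusion, partition-ratio domain clipping); multiplicative hazard
    scores benchmarked as percentile ranks against a reference set of
    well-characterized contaminants; molecular-formula composition
    analytics; and a reproducible synthetic chemical-property generator for
    testing the full pipeline without proprietary input data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
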