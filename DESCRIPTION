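Package: camtrapRD
Title: Robust-Design Capture-Recapture for Long-Term Camera-Trap Monitoring
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for open-population analysis of long-term camera-trap
    studies of individually identifiable animals. Builds robust-design
    capture histories from time-stamped detection events (24-hour
    independence filtering, weekly secondary occasions, survey-gap aware
    primary layout), fits Huggins-style conditional robust-design models
    with a three-state hidden Markov likelihood (apparent survival,
    random or Markovian temporary emigration, sex- and camera-era
    structured detection), ranks and averages models by AICc, and derives
    abundance, population growth, recruitment, longevity, residency and
    detection-frequency statistics. Includes a synthetic event generator
    with a truth ledger, calibrated to a 14-year jaguar monitoring
    program, for validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'survey-design.R'
    'events.R'
    'capture-history.R'
    'mark-inp.R'
    'model-structure.R'
    'likelihood.R'
    'fit.R'
    'abundance.R'
    'model-average.R'
    'demography.R'
    'population-structure.R'
    'simulate.R'
    'reference-data.R'
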