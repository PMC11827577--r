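Package: phenosync
Title: Phenological Synchrony-Asynchrony Indices with a Dynamic
    Meteorological Dimension
Version: 0.1.0
Authors@R:
    person("Phenosync", "Developers", email = "phenosync@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying phenological synchrony and asynchrony
    across trophic levels (vegetation green-up, insect first flight,
    migrant-bird arrival) while accounting for the critical weather
    windows that precede each event.  Includes extraction of green-up
    dates from NDVI time series by the half-amplitude method, gridding
    and filtering of citizen-science occurrence records, a relative
    sliding time-window regression engine with AICc model selection and
    randomisation significance, the AL / AL-prime / QAI / WO / IICWM
    interaction-index family, trophic-network export, and a synthetic
    data generator with planted ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
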