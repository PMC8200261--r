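Package: concernews
Title: Behavioral Early-Warning Scores from Clinician Documentation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates hospital encounter event streams in which nurses'
    documentation behavior (extra vital-sign measurements, flowsheet
    comments, PRN administrations, withheld scheduled medications, nursing
    notes) intensifies tens of hours before a composite deterioration event
    while physiological abnormality appears only in the final hours.
    Extracts an hourly behavioral feature matrix (common/uncommon-time
    expansion, trailing 12-hour aggregation), fits a discrete-time logistic
    reference scorer emitting green/yellow/red hourly risk categories,
    computes MEWS and NEWS physiology comparators, and evaluates all scores
    with a time-varying-covariate Cox proportional-hazards model and a
    lead-time likelihood-ratio statistic L(x, h).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
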