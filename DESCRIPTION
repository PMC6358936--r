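Package: drivesense
Title: Steering-Wheel and Physiological Signal Analytics for Driver Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse driver state from a steering-wheel gyroscope and
    wearable physiological sensors recorded alongside a driving simulator.
    Extracts steering features from angular-speed traces (wheel-position
    integration, complete-turn counting, zero-crossing and running-maximum
    event detection, five-interval angular-speed histograms, windowed
    statistics) and classifies five-second low-attention periods. Processes
    ECG into R-peak series and heart-rate-variability summaries and EMG/GSR
    into windowed channel statistics. Includes a seeded synthetic-session
    simulator (alert/drowsy steering regimes, rested/tired physiology,
    one-hertz vehicle telemetry, traffic-offence events, sleepiness
    questionnaires), a correlation-study pipeline (offence-rate
    normalisation, Shapiro-Wilk screening, Pearson correlation with
    significance filtering), a TCP session-synchronisation and file-transfer
    protocol, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
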