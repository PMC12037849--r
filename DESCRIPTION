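Package: imuapnea
Title: Sleep Apnea Screening from Body-Worn Inertial Sensor Signals
Version: 0.1.0
Authors@R: person("IMU Apnea", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects sleep-apnea-related respiratory events in tri-axial
    accelerometer and gyroscope recordings from devices worn on the
    abdomen. Extracts a respiratory amplitude series (band-pass 0.13-0.7
    Hz, per-axis, Euclidean norm) and a respiratory frequency series
    (dominant-axis waveform, negative-to-positive zero crossings), detects
    events as sustained >30% reductions of the fast 95th-percentile
    envelope below the slow envelope (amplitude) or of the frequency below
    its upper envelope, converts hourly event indices into an estimated
    apnea-hypopnea index via device-specific regression models, classifies
    severity, and evaluates breath-by-breath concordance against
    polysomnography-style annotations. Includes a synthetic overnight
    recording generator with ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
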