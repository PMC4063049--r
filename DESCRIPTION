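Package: fallfusion
Title: Context-Aware Fall-Risk Assessment by Fusing Wearable and Ambient Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A complete pipeline for context-aware fall-risk assessment in
    ambient assisted living. A threshold-based wearable fall detector computes
    an impact statistic and device orientation from tri-axial accelerometer
    streams; an activity-recognition engine turns environmental sensor
    readings into temporal intervals and infers activities of daily living
    through Allen interval-algebra rules; a discrete two-slice dynamic
    Bayesian network fuses both evidence channels per time slice and yields a
    posterior fall-risk probability used to confirm or reject raw fall
    alarms. Includes exact inference (filtering, smoothing, prediction, MAP
    sequences), EM parameter learning, a brute-force enumeration oracle, and
    synthetic generators for accelerometer traces, sensor events and
    monitoring scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
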