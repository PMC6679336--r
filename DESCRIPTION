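Package: flockdrift
Title: Hybrid Offline Nearest-Prototype and Online k-Means Classification
    of Sheep Behaviour Under Concept Drift
Version: 0.1.0
Authors@R:
    person("flockdrift", "maintainers", email = "maintainers@flockdrift.org",
           role = c("aut", "cre"))
Description: Classifies walking, standing and lying behaviour of sheep from
    ear-mounted tri-axial accelerometer and gyroscope streams. Combines a
    capacity-limited byte-quantised nearest-prototype classifier (an
    emulation of an on-chip pattern matching engine) with an online
    streaming k-means learner over the windowed mean acceleration
    magnitude, fusing the two through a learned decision-rule table so the
    system adapts to concept drift in long-term deployments. Includes
    window segmentation and feature extraction at the device cadence,
    one-vs-rest performance metrics with macro averaging, a seeded
    synthetic behaviour/IMU generator with injectable distribution drift,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
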