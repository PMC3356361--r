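Package: gliderpam
Title: Passive Acoustic Monitoring of Odontocete Echolocation Clicks from
    Glider Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for glider-based passive acoustic surveys of deep-diving
    toothed whales. Simulates broadband echolocation click trains, noise and
    whole recording missions with ground truth; detects click transients with
    a band-energy-ratio (ERMA-style) spectrogram detector; measures the
    discriminating click features (duration, -20 dB low-frequency roll-off,
    peak frequency, FM upsweep, band-limited zero-to-peak SNR, inter-click
    intervals); classifies click trains to species group with an explicit,
    configurable rule set; aggregates detections into mission statistics
    (per-class file percentages, diel profiles, day/night one-way ANOVA,
    encounter counts and rates, detector performance accounting); and matches
    glider tracks against satellite-tag surfacing fixes with a great-circle
    distance and fix-accuracy rule, including hypothetical dive-profile
    reconstruction and recording-overlap computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
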