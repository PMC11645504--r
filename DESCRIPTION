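Package: oculomark
Title: Digital Eye-Tracking Biomarkers for ADHD Screening from Saccade Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and analysis of digital eye-tracking biomarkers from
    prosaccade, antisaccade and delayed-saccade tasks for auxiliary screening
    of attention-deficit/hyperactivity disorder (ADHD). Provides screen and
    area-of-interest geometry, velocity-threshold (I-VT) fixation and saccade
    detection, robust pupillometry preprocessing with median-absolute-deviation
    outlier rejection, stationary and transition gaze entropy, a 28-biomarker
    catalog expanded into a 183-variable participant feature table,
    group-comparison statistics, a repeated cross-validated gradient-boosted
    classifier with split-gain variable importance, and a synthetic gaze-data
    generator for end-to-end validation without real recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
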