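Package: onoffgait
Title: Mapping ON/OFF Motor Fluctuations in Parkinson's Disease from
    Waist-Worn Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects ON/OFF motor fluctuations in Parkinson's disease from a
    single waist-worn triaxial accelerometer. The pipeline detects walking in
    3.2-second windows with an RBF-kernel support vector machine over spectral
    band-power features, segments strides from initial-contact events in the
    forward trunk acceleration, scores each stride's gait fluency as spectral
    power in the 0.1-10 Hz band, and classifies walking episodes as ON or OFF
    against a patient-specific threshold fitted with a linear-kernel
    maximum-margin separator. Includes the full diary-based validation
    protocol (transition margins, intermediate/undefined exclusion, repeated
    random calibration splits) and a synthetic waist-acceleration simulator
    with ground-truth walking bouts, contacts, and motor-state timelines.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
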