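Package: gtol
Title: Cardiac Force Index Processing and G-Tolerance Prediction for Aircrew
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes 1 Hz wearable chest-strap sensor streams (heart rate,
    triaxial-accelerometer activity, signal-confidence channels) into the
    cardiac force index (CFI = weight x activity / heart rate), including
    signal-confidence quality filtering, squat-marker phase segmentation of a
    rest/walk ground protocol, and two-minute window averaging into the
    resting CFI (RCFI), walking CFI (WCFI) and cardiac force ratio
    (CFR = WCFI/RCFI). Houses published linear equations predicting
    relaxed and straining G tolerance (RGT, SGT) from WCFI and demographics,
    an ordinary-least-squares fitter with p-value-driven stepwise selection,
    Pearson correlation analysis, and observed-versus-estimated model checks.
    A calibrated synthetic cohort and sensor-stream generator reproduces the
    statistical structure of the development cohort so the entire pipeline is
    testable end to end without access to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
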