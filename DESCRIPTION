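Package: wristflex
Title: Detecting Finger and Wrist Movements from a Single Wrist-Worn
    Inertial Measurement Unit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the occurrence of finger and wrist flexion-extension
    movements from a single wrist-worn inertial measurement unit (IMU).
    Nine motion channels (gravity-compensated linear acceleration, angular
    velocity, and gravity direction from a Madgwick orientation filter)
    are windowed, converted to short-time Fourier transform spectrograms,
    Box-Cox normalized, and classified with a compact convolutional neural
    network trained with binary cross-entropy. Includes motion-capture
    based labeling of movement events, subject-grouped cross-validation,
    speed-stratified evaluation, label-noise accuracy bounds, and a seeded
    synthetic-session generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
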