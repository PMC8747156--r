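Package: perturbalance
Title: Perturbation-Based Standing Balance Assessment for Humans and Exoskeletons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking standing balance of humans with or without a
    lower-limb exoskeleton under manually delivered push perturbations. Provides
    calibration and event detection for a hand-held instrumented perturbator
    (3-axis force, IMU orientation) and a pressure-sensing garment, a
    16-condition validation protocol with controlled-variable tolerance checks
    (magnitude, duration, orientation, location), a planar five-segment
    link-segment centre-of-mass model with combined human + exoskeleton sway
    angles, balance indicators (peak body sway, recovery time), and a synthetic
    session generator with ground-truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
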