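Package: tendonmech
Title: Freehand 3D Ultrasound Tendon Morphology and Mechanics Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for acute tendon-loading studies of
    the free Achilles tendon. Reconstructs tendon length, cross-sectional area
    and volume from tracked, segmented freehand 3D ultrasound sweeps; corrects
    net plantarflexion torque for antagonist co-contraction via a linear
    EMG-torque model and resolves tendon force through the moment arm;
    estimates stiffness from force-elongation and Young's modulus from
    stress-strain fits over staged contraction levels; and analyses crossover
    trial outcomes with repeated-measures ANOVA, interaction contrasts,
    change-score effect sizes, and ICC/SEM/MDC reliability metrics. A
    synthetic-data generator with closed-form ground truth (tendon phantoms,
    tracked sweeps, EMG/torque trials, crossover datasets) makes every stage
    testable without real ultrasound or dynamometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nortest,
    signal,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
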