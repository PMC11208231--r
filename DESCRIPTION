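Package: tmsmap
Title: TMS Motor-Cortex Mapping, Sensorimotor Testing and Multivariate
    Mixed Models for Low Back Pain Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for case-control studies of primary
    motor cortex organization in low back pain. Extracts motor evoked
    potentials (MEPs) from TMS-mapping EMG (30 Hz high-pass, 500 ms
    epochs, peak-to-peak detection with amplitude thresholds), computes
    amplitude-weighted centre-of-gravity and cortical map area
    (alpha-shape or convex hull on the best-fit plane), scores spiral
    tracking trials and a quantitative sensory testing battery, and
    fits multivariate two-level mixed models (Group x Test interaction
    with a subject random intercept) for group differences and
    map-behaviour associations. Includes a synthetic-cohort generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lme4,
    nlme,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
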