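Package: hitd
Title: Functional Head Impulse Testing: Simulation and Analysis of VOR Reading Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for functional testing of the angular vestibulo-ocular
    reflex (VOR) with the head impulse testing paradigm: an optotype is
    flashed on screen when head angular acceleration crosses a threshold and
    the subject reports its orientation. Provides a ground-truth-annotated
    simulator of head impulses, healthy or deficient eye responses with
    covert/overt corrective saccades, frame-quantized display timing with a
    photodiode channel, and probabilistic reading answers; plus the full
    analysis chain: gravity-referenced yaw velocity from head-mounted
    gyroscopes, online-style thrust detection, VOR gain over the
    peak-acceleration to peak-velocity interval, acceleration binning with
    per-bin reading performance and protocol planning, gaze and retinal-slip
    reconstruction, saccade detection and covert/overt labeling, Landolt C
    optotype sizing, a QUEST adaptive static-acuity staircase, psychometric
    fitting, a plain-text session file format and report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
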