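Package: swayagree
Title: Stabilometric Parameters and Device Agreement for Balance-Board Posturography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for assessing whether consumer balance boards can be used
    interchangeably with a laboratory force plate for quiet-stance posturography.
    Reads raw corner-load and force/moment recordings, derives center-of-pressure
    (CoP) trajectories (uniform resampling, zero-phase Butterworth low-pass),
    computes nine stabilometric parameters (sway path, 95% prediction ellipse
    area, per-axis dispersion, amplitude and mean velocity, total mean velocity),
    and runs the device-agreement battery: paired force-plate minus board
    differences, 95% limits of agreement with out-of-limit contingency and
    chi-square, two-way random-effects intraclass correlation (single and
    average forms with F-based confidence bounds), Friedman repeated-measures
    tests, and Spearman correlations. A synthetic paired-device study generator
    (Ornstein-Uhlenbeck sway, miscalibrated quad-load-cell board model,
    force-plate wrench model) emulates a crossover design so the whole chain is
    testable without hardware.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
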