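Package: toolgaze
Title: Gaze-Bias Analysis for Tool-Viewing Eye-Tracking Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for screen-based eye-tracking experiments in
    which observers view elongated tools under different action demands.
    Implements velocity-threshold (I-VT) fixation classification at the
    native sampling period, subject-averaged region-of-interest (ROI)
    construction for functional and grasping tool parts, a standardized
    horizontal gaze coordinate anchored at the tool center and the ROI
    outer edges, cumulative fixation-time and time-binned gaze metrics,
    and the within-subjects statistical battery (balanced two-way
    repeated-measures ANOVA, Shaffer sequentially rejective multiple
    comparisons, Mann-Whitney U, and a variance-ratio-gated t test).
    A synthetic scanpath generator with known ground truth emulates the
    full experimental design for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
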