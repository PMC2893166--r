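Package: loopmaa
Title: Loop-Design Two-Color Microarray Analysis with a Two-Stage Mixed Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing two-colour microarray
    experiments laid out as dye-swapped loop designs. Implements a two-stage
    mixed linear model: stage one fits global panel, dye and treatment fixed
    effects together with array and dye-within-array variance components
    (balanced-design method of moments, with an optional REML refinement);
    stage two refits per-probe fixed-effect models on the stage-one residuals
    and computes F tests, pairwise t tests and Wilcoxon rank-sum tests,
    p-value ranking, and top-k profiling: direction-of-regulation calls,
    treatment-similarity (Venn) partitions, functional-category summaries,
    heat-map matrix export and cross-platform sign concordance. A synthetic
    two-channel data generator with ground truth supports calibration and
    recovery testing, and summary statistics are provided for egg-hatch and
    host-location fitness assays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), lme4, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
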