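Package: relex
Title: Reliability Extrapolation and Study Feasibility for Test-Retest Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciding, before data collection, whether a planned
    individual-differences study can answer its question given the measurement
    reliability of its outcome. Estimates test-retest reliability (the
    two-way mixed-effects, absolute-agreement, single-measurement intraclass
    correlation, ICC(A,1)) from raw long-format data, converts between ICC,
    standard error of measurement (SEM), within-subject coefficient of
    variation and smallest detectable differences, and extrapolates a
    published ICC to a new sample with different variability using only
    summary statistics. Includes effect-size attenuation corrections for
    unreliable measures, the combined two-group sample algebra needed to find
    the group separation at which a target reliability is reached,
    reliability-aware power analysis for correlations (Fisher z) and t-tests
    (exact noncentral t), a synthetic test-retest data generator with known
    variance components, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
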