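Package: breathkit
Title: Whole-Body Plethysmography Breath Segmentation, QC, and Respiratory Metrics
Version: 0.1.0
Authors@R: person("breathkit", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing whole-body plethysmography recordings from
    rodents: breath segmentation from calibrated flow traces, an artifact
    rejection cascade (per-breath duration and volume-ratio rules plus a
    sliding-window fast-breathing filter), the interbreath-interval
    irregularity (IBII) statistic, per-animal respiratory summaries
    (frequency, tidal volume, minute ventilation), and one-way ANOVA group
    comparisons across genotypes. Includes a synthetic respiratory waveform
    generator with phenotype presets and injectable artifacts so the whole
    pipeline can be validated against a known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
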