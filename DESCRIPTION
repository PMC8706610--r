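Package: cusumbench
Title: CUSUM Learning-Curve Assessment and Pentafecta Benchmarking for
    Surgical Case Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing surgical learning curves from consecutive
    case series: retrospective continuous CUSUM trajectories, binary
    competence CUSUM with Wald sequential probability ratio test (SPRT)
    control limits, an operative-time plateau rule based on consecutive
    sub-threshold runs, and quintile benchmarking of the five Pasadena
    consensus pentafecta criteria (operative time, haemoglobin drop, severe
    complications, surgical margins, lymph-node yield) with a uniform
    failure-rate threshold. Includes a calibrated synthetic cohort
    generator with a phase-structured learning curve so the full pipeline
    can be exercised and tested without patient data, plus CSV interchange
    and report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
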