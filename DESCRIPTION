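Package: spectriage
Title: Cost-Effectiveness Modelling of a Serum-Spectroscopy Triage Test for
    Brain Tumour Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-tree cost-effectiveness models for a blood-serum
    spectroscopy triage test inserted into the brain-tumour diagnostic
    pathway, with primary-care and secondary-care entry points and an
    imaging-only comparator. Provides typed model parameters with UK and
    USA unit-cost tables, a generic chance/terminal decision-tree engine
    with expected-value rollback, calibration of the unpublished
    survival-gain and avoided-workup quantities against the published
    incremental results, incremental cost-effectiveness analysis (QALYs,
    costs, ICERs, dominance, net monetary benefit), one-way and scenario
    sensitivity analyses with threshold search, probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, and a seeded
    patient-level microsimulation that acts as a Monte-Carlo oracle for
    the analytic tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
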