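Package: rfdosim
Title: Whole-Body RF-EMF Dosimetry and Synthetic Rodent Cohort Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form far-field dosimetry for rodent radiofrequency
    electromagnetic field (RF-EMF) exposure experiments: incident power
    density under the inverse-square law, cage-averaged whole-body specific
    absorption rate (SAR), and ICNIRP compliance checking. Also provides a
    seeded synthetic-cohort generator calibrated to published group
    statistics of a five-week Wistar rat exposure study (weekly body
    weights, rectal and skin temperatures, terminal organ masses, Morris
    water maze trials with censoring and passive-swimming flags), endpoint
    computation (weight-gain dynamics, organ weight coefficients,
    temperature differentials, daily maze summaries), and an exact
    Mann-Whitney U test for exposed-versus-control comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
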