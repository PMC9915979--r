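Package: benzrisk
Title: Reverse-Dosimetry PBPK Exposure Reconstruction and Risk
    Characterization for Benzene Biomonitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs inhaled benzene air concentrations from urinary
    trans,trans-muconic acid (tt-MA) measurements via a four-compartment
    steady-state physiologically based pharmacokinetic (PBPK) model with
    Michaelis-Menten hepatic metabolism, and characterizes the resulting
    health risks with the EPA inhalation framework: scenario-averaged
    chronic exposure, hazard quotients against the reference concentration,
    leukemia risk from inhalation unit risk bounds, and expected case
    burdens for an exposed child population. Includes cohort filtering with
    limit-of-quantification and albumin/creatinine exclusion rules, a
    seeded synthetic-cohort generator for testing every pipeline stage,
    and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
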