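Package: tcelltwin
Title: Digital Twins for the Cellular Kinetics of TCR-Engineered T Cell Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative systems pharmacology (QSP) model of the cellular
    kinetics of TCR-engineered T cell therapy in solid tumours, and the
    digital-twin workflow built on top of it.  The model tracks four
    engineered memory phenotypes (stem cell-like memory, central memory,
    effector memory, effector) and endogenous T cells across blood,
    tumour-draining lymph node, lumped normal tissue and tumour, with
    homeostatic and antigen-driven proliferation, differentiation,
    apoptosis, trafficking and lymphodepletion.  The package screens
    virtual patients against per-patient longitudinal blood measurements
    to select digital twins, simulates virtual clinical trials and
    dose-composition sweeps, classifies persister outcomes, performs
    partial-rank-correlation and principal-component sensitivity
    analyses, and ships a synthetic-data generator that emulates the
    structure of the calibration trial.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
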