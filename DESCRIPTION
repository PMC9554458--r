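Package: gentapbpk
Title: Minimal PBPK Modelling and Dosing Evaluation of Gentamicin in Neonates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Minimal physiologically-based pharmacokinetic (PBPK) model of
    gentamicin in preterm and term neonates: a four-state flow-limited
    kidney / rest-of-tissues / heart-chamber / blood-pool ODE system with
    glomerular-filtration elimination corrected for tubular reabsorption.
    Provides seeded Monte Carlo virtual populations with log-normal
    inter-individual variability, PK/PD probability-of-target-attainment
    (Cmax/MIC, T>MIC, trough and peak toxicity) evaluation of conventional
    and extended-interval dosing regimens, predictive-performance metrics
    (MPE, AFE, AAFE) and visual predictive checks, iterative two-stage
    population estimation of glomerular filtration rate from therapeutic
    drug monitoring data, and a synthetic TDM-study generator emulating a
    neonatal 2 h / 24 h sparse sampling design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
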