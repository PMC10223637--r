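Package: milkPBPK
Title: Bottom-Up Prediction of Medicine Concentrations in Human Milk
Version: 0.1.0
Authors@R: person("Lactation PK", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semi-mechanistic prediction of medicine transfer into human milk
    during lactation. Predicts bidirectional plasma-milk secretion and reuptake
    clearances and milk binding from physicochemical properties (LogP, polar
    surface area, hydrogen-bond donors, pKa, plasma protein binding), couples
    them to a reduced compartmental maternal pharmacokinetic model with a
    fixed-volume milk compartment, and computes AUC-based milk-to-plasma
    ratios, daily and relative infant doses, and Monte-Carlo population
    percentile bands. Ships physicochemical records for ten physicochemically
    diverse model medicines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
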