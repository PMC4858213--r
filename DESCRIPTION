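Package: isnet
Title: Steady-State Modelling of the Insulin Signalling Network with
    Linked Cell-Population Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Normalized Michaelis-Menten steady-state model of the insulin
    signalling network (IR, IRS1, PI3K, PIP3, PDK1, mTORC2, three-state Akt
    phosphorylation at Thr308/Ser473, FoxO1, GSK3beta, mTORC1, S6K1, GLUT4)
    with negative and positive feedback loops, solved by a two-variable
    fixed-point reduction.  Includes named experimental condition presets
    (PTEN silencing, insulin-resistant db/db medium, rapamycin, PP242,
    UCN-01), bound-constrained derivative-free least-squares parameter
    estimation from dose-response tables, log-log sensitivity analysis, a
    TSC2/Rheb/PRAS40 mTORC1-activation submodel, an age-structured
    cell-cycle population model with closed-form phase fractions and
    labeling index, link analysis between signalling outputs and population
    kinetics under mTOR inhibition, and synthetic-data generators with
    known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
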