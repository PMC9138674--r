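Package: ecisfence
Title: Electric-Fence ECIS Analysis of Cell Attachment, Migration and
    Micromotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for electric cell-substrate impedance sensing
    (ECIS) experiments that use the electric-fence protocol to quantify cell
    migration on coated microelectrodes. Implements the forward
    cell-electrode impedance model for cell-free and cell-covered 250-um
    gold electrodes and the inverse fit that extracts junctional resistance
    (Rb), cell-substrate separation (h) and membrane capacitance (Cm) from
    multi-frequency impedance scans; attachment and migration kinetics
    (capacitance/resistance slopes, T50, adhesion-stage segmentation by
    optimal piecewise-linear partitioning); the Var32 micromotion
    fluctuation statistic; closed-form physico-chemical calculators
    (Helmholtz-Smoluchowski zeta potential, alamarBlue reduction and
    relative adhesion, electric-fence voltage, cell radius from area); and a
    seeded synthetic-signal generator that emulates the instrument so every
    stage is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
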