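Package: pdmix
Title: Response-Surface Modelling and Mixing Simulation for Microfluidic
    Liposome Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling liposome synthesis in a periodic-disturbance
    micromixer. Builds the two-factor central composite rotatable design over
    total flow rate (TFR) and flow rate ratio (FRR), fits and reduces quadratic
    response-surface models for liposome size (Z-average), polydispersity index
    and zeta potential with PRESS-based predicted R-squared and constrained
    optimisation, groups design conditions with Tukey-Kramer compact letter
    displays, and provides a desk-scale two-dimensional laminar flow and
    species-transport simulator of the mixing channel with the Danckwerts
    intensity-of-segregation mixing-efficiency profile. A synthetic run-table
    generator emulating the study's noise structure makes every stage testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
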