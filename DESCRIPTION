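Package: pulsarch
Title: Rheology-Aware Pulsatile Hemodynamics of an Idealized Aortic Arch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis of how blood rheology reshapes pulsatile
    hemodynamics in the aortic arch. Implements a Carreau shear-thinning
    viscosity model with parameter sets for anemic, diabetic and two healthy
    blood conditions, a piecewise-sinusoidal cardiac inlet waveform,
    three-element Windkessel (RCR) outlet boundary conditions with a
    backward-Euler pressure update, and a radially resolved non-Newtonian
    pulsatile tube solver standing in for the three-dimensional arch.
    Post-processing covers wall shear stress, skin friction, pressure
    gradients, helicity diagnostics on gridded velocity fields, and an
    illustrative hemodynamic severity classification. Analytic references
    (Womersley, Poiseuille, Arnold-Beltrami-Childress flow) are generated
    in closed form for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
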