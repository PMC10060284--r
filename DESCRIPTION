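Package: plaquesim
Title: Free-Boundary Multiphase Simulation of Early Atherosclerotic Plaque Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates early atherosclerotic plaque growth as a one-dimensional
    free-boundary multiphase mixture of macrophage foam cells, modified
    low-density lipoprotein (modLDL) and dead cellular material that together
    fill the artery-wall intima. Phase kinetics couple phagocytosis of modLDL,
    foam-cell death and efferocytic uptake of dead material; transport combines
    random motility, chemotaxis towards modLDL and dead material, and a
    closed-form mixture velocity implied by the no-voids constraint. Flux
    boundary conditions model endothelial LDL deposition and modLDL-dependent
    monocyte recruitment, and lymphatic emigration of foam cells through the
    moving medial boundary. The solver maps the growing domain onto a fixed
    grid and advances the semi-discrete system with a stiff backward
    differentiation formula integrator. Includes the deep-plaque reduction of
    the kinetics to a logistic characteristic ordinary differential equation
    (steady states, stability, transcritical bifurcation), a conserved bead
    tracer extension for continuum macrophage tagging with
    full-width-at-half-maximum circulation times, parameter-sweep drivers, and
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
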