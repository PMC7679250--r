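Package: biosensim
Title: Control-Volume Finite-Element Simulation of Microfluidic Biosensors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates analyte transport and capture in a microfluidic-channel
    biosensor. Solves the steady incompressible Navier-Stokes equations on a
    structured quadrilateral mesh with a control-volume based finite-element
    method (CVFEM), using Karimian-Schneider momentum interpolation for
    pressure-velocity coupling on a collocated grid and a physical influence
    scheme (PIS, streamline-upwind) closure for convected quantities. The
    frozen flow field drives convection-diffusion of a dilute analyte coupled
    to Langmuir-Hinshelwood adsorption-desorption kinetics on a functionalized
    sensor strip, producing binding-cycle sensorgrams. Includes closed-form
    oracles (Poiseuille flow, well-mixed Langmuir kinetics), manufactured-
    solution convergence cases, a packaged validation configuration, VTK
    legacy output and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
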