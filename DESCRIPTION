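Package: ilsmap
Title: Implicit Ligand Sampling Free-Energy Maps and Catalytic-Loop Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing of molecular dynamics ensembles to map the
    three-dimensional free energy of a weakly interacting gas probe
    (implicit ligand sampling / Widom test-particle insertion), extract
    gas migration pathways and their minimax free-energy barriers from
    the resulting volumetric maps, and quantify catalytic-loop gating
    dynamics (opening angle, contact distance, helical content,
    correlation times, principal component analysis and GROMOS
    RMSD clustering). Includes seeded Monte Carlo generators for rigid
    water boxes, Lennard-Jones fluids, cavity-channel wall systems and
    two-basin loop trajectories so the whole pipeline is testable
    without external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
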