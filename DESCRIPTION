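Package: gcosc
Title: Chemokine-Driven B-Cell Migration Oscillations in the Germinal Center
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic models of germinal-center B-cell
    migration driven by chemokine-induced receptor down-regulation. Provides
    static Gaussian chemokine fields (CXCL12/CXCL13) with voxel-grid
    discretization, a toy and a biologically motivated receptor/chemotaxis
    ODE model (CXCR4/CXCR5), adaptive ODE and Euler-Maruyama SDE
    integration, equilibrium continuation with Hopf and fold detection,
    trajectory phenotyping (symmetric, asymmetric, intrazonal, nested and
    chaotic oscillations), and a 3D stochastic individual-based simulation
    of migrating cells over discretized chemokine fields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
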