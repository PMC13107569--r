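Package: mtlength
Title: Microtubule Length Regulation by Depolymerizing Motors at Both Ends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multiscale modelling of non-centrosomal microtubule length
    regulation by two classes of depolymerizing kinesin motors (a slow,
    processive plus-end-directed species and a diffusive minus-end-directed
    species). Implements the full moving-domain advection-diffusion-reaction
    system for bound and unbound motor densities coupled to tip dynamics at
    both filament ends, solved by an arbitrary Lagrangian-Eulerian
    reference-domain scheme; its fast-switching (quasi-steady-state)
    reduction with effective transport coefficients and Robin boundary
    conditions; the adiabatic one-dimensional length flow with closed-form
    steady motor profiles, equilibrium existence and uniqueness analysis,
    and the Lambert-W fixed-end nullcline condition; and tools for regime
    classification (disassembly, treadmilling, fixed ends, growth),
    parameter sweeps, configuration files, and reproducible scenario runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
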