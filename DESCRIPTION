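Package: lymphomog
Title: Multiscale Dual-Porosity Flow in the Lymph Node
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for pulsatile perfusion of a vascularized lymph node as a
    dual-porosity medium. Periodic-cell homogenization solvers compute effective
    hydraulic conductivities: a Darcy cell problem for the blood-vessel network
    and a frequency-domain Brinkman cell problem whose complex, frequency-dependent
    conductivity is the Fourier-domain face of a Darcy law with memory. A spectral
    macroscale solver evaluates the coupled Darcy/Darcy-with-memory equations on a
    sphere by Legendre-mode projection and modified spherical Bessel radial
    solutions, with Starling transvascular exchange. Application-level routines
    reproduce baseline perfusion, parameter sweeps, the flow-inversion threshold
    of the mean blood-vessel pressure, and conductivity sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
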