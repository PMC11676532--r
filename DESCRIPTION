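Package: katytw
Title: Reduced-Order Travelling-Wave Mechanics of the Katydid Inner Ear
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fluid-loaded segment-chain (transmission-line) model of the
    katydid inner ear: the tapering dorsal wall that carries the crista
    acustica is reduced to a chain of two-degree-of-freedom mechanical
    segments coupled through the auditory-vesicle fluid. The package builds
    parametric synthetic geometry, assembles the per-segment mechanical
    network, solves the line in the frequency and time domains, extracts
    travelling-wave diagnostics (tonotopic maps, envelope asymmetry,
    accumulated phase lag), calibrates the stiffness gradient to printed
    peak-position anchors, and reimplements the auditory-vesicle fluid
    microrheology pipeline (synthetic Brownian trajectories, particle
    localization and linking, mean-squared displacement, Stokes-Einstein
    viscosity recovery) end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
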