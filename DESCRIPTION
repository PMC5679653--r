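Package: hemoflow
Title: Ventricular Hemodynamics from 4-D Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to recover beating-ventricle wall motion from time-resolved
    3-D image stacks by cubic B-spline free-form deformable registration, to
    build watertight capped surface and simplex volume meshes of the cavity,
    to simulate incompressible blood flow in the moving domain with a
    variational-multiscale (VMS) stabilized arbitrary Lagrangian-Eulerian
    (ALE) finite-element solver, and to compute mechanobiologic force metrics:
    wall shear stress (WSS), area- and time-averaged WSS, oscillatory shear
    index (OSI), kinetic energy density, viscous dissipation, stroke volume
    and ejection fraction. Includes a synthetic beating-ventricle phantom
    generator with analytic ground truth, manufactured-solution flow cases
    for solver verification, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    tiff,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
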