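Package: mechcompete
Title: Mechanical Cell Competition: Phase-Field Simulation, Stress
    Statistics and Traction-Based Force Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying mechanical competition between two epithelial
    cell populations that differ in cell-cell and cell-substrate adhesion.
    Provides a three-dimensional multiphase-field simulator of an active cell
    monolayer on a rigid substrate (deformable cells, differential adhesion,
    contact-inhibition-of-locomotion polarity, emergent cell extrusion), the
    fluctuation and extrusion statistics used to characterise the active
    interface (stress susceptibility, spatial autocorrelation and correlation
    length, interface-distance statistics of extrusion events, ensemble stress
    maps around extrusions, interface convexity), an analytic energetics model
    of the work needed to eliminate a cell through a constant-volume
    cylinder-cone-sphere shape sequence, and a force-inference chain from
    substrate displacements to tissue stress (regularized Fourier-transform
    traction cytometry and Bayesian inversion stress microscopy), together
    with synthetic-data generators that make every stage testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    Matrix,
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    EBImage,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
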