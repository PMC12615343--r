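Package: rheoprint
Title: Rheology-Based Printability Analysis for Extrusion 3D Food Printing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking oscillatory rheology of yield-stress food inks to
    their 3D-printing performance. Fits a descriptive amplitude-sweep model
    (LVE modulus, loss factor, critical strains, strain-thinning indices) to
    storage/loss modulus data, derives the yield stress and Herschel-Bulkley
    extrusion-force and self-support predictions, quantifies printed-object
    fidelity from top-view photographs via image moments, annulus radii and a
    dimensionless deviation metric, and provides the correlation, data-collapse
    and printability-window statistics that relate the two. Includes synthetic
    generators (noisy sweeps, rendered top-view fixtures, correlated ink
    cohorts) so the full pipeline is testable without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    minpack.lm,
    EBImage,
    png,
    yaml,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
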