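Package: agephantom
Title: Age-Scalable 3D Computational Phantom with DICOM RT Structure Export
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scales a generic adult computational phantom (body-region cuboids
    plus organ point grids) to any age from 0.1 to 18 years using piecewise-linear
    growth-based scaling factors, transforms the geometry into the DICOM patient
    coordinate frame (head-first supine), and exports it as a DICOM RT Structure
    Set with an optional synthetic water-equivalent CT series, for retrospective
    organ dose reconstruction in late-effects studies of childhood cancer
    survivors. Includes the geometric validation metrics used for such phantoms:
    percent differences, normalized mean square distance between organ point
    grids, height comparison against population reference tables, and organ
    masses from voxelized convex-hull volumes and reference tissue densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
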