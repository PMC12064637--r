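Package: osteoplan
Title: Automatic Positioning of Cutting Planes for Bone Tumor Resection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Plans the placement of n coincident cutting planes, all parallel to a
    single surgical-access direction, for bone tumor resection with patient-specific
    cutting guides. The cutting surface is the vertical extrusion of an open polygonal
    chain of n+1 points in the access plane; its 2(n+1) coordinates are optimized by
    particle swarm optimization to minimize resected healthy bone while guaranteeing
    complete removal of the safety-margin-expanded tumor. Includes triangle-mesh
    infrastructure (STL/PLY input and output, signed volumes, mesh splitting by the
    extruded surface), validity checks with penalty handling, a convex-hull-derived
    warm start, synthetic bone/tumor phantoms with a known analytic optimum, and a
    command-line workbench.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
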