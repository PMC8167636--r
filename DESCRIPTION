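Package: splintfea
Title: Finite-Element Biomechanics of Mandibular Dentition and Occlusal Splints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for personalised biomechanical analysis of the mandibular
    dentition under occlusal load. Converts relative T-Scan occlusal
    measurements to absolute per-tooth forces through a linear calibration,
    generates a synthetic dentition stand-in (voxel Hounsfield-unit phantom
    with threshold segmentation, parametric tooth/periodontal-ligament/splint
    solids, and a conforming background-grid tetrahedral mesh), solves the
    linear-elastic boundary-value problem with constant-strain tetrahedra,
    and post-processes displacements and von Mises stresses into per-tooth
    maxima, between-scenario comparisons, and safety checks against
    physiological and material thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
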