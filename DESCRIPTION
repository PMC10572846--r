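Package: fpetkin
Title: Double-Bolus Functional FDG-PET Kinetic Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of task-evoked changes in cerebral glucose
    metabolism from a single dynamic FDG-PET acquisition with two tracer
    boli (baseline and activation sessions). Implements the irreversible
    two-tissue compartment model solved piecewise across the session
    boundary, a non-invasive image-derived input function (vessel
    segmentation, dilation, background correction), a staged constrained
    voxelwise least-squares fit producing Ki, V0 and relative-change (delta
    Ki) parametric maps, and a digital double-bolus phantom simulator so
    the whole pipeline can be exercised without scanner data. Includes
    minimal NIfTI-1 volume input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
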