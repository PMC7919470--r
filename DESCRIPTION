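Package: arguide
Title: Patient-Specific Surgical Guides with Cubic AR-Marker Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of an augmented-reality plus
    3D-printing workflow in orthopedic oncology: post-processing of CT
    segmentation masks (thresholding, island removal, morphological hole
    filling, surface extraction), design of patient-specific surgical guides
    as negative extrusions of a bone patch with screw holes, conical
    registration fiducials and a holder for a 30 mm cubic augmented-reality
    marker, rigid-transform algebra with closed-form point-based registration
    (fiducial and target registration errors), a synthetic-phantom generator
    reproducing a six-case validation protocol (guide placement error and
    end-to-end AR tracking error, two users by five repetitions), and summary
    statistics including paired user tests, distance-error correlation and
    Likert survey tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
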