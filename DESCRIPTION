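Package: multipose
Title: Computational Core for Multi-Animal Pose Estimation and Tracking
Version: 0.1.0
Authors@R:
    person("Pose", "Tools Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Non-neural computational core of a multi-animal pose-tracking
    pipeline: encoding of labeled poses into gridded training targets
    (part confidence maps, part affinity fields, class maps), decoding of
    those targets back into per-animal instances (local/global peak finding
    with integral subpixel refinement, bottom-up part-affinity grouping and
    top-down anchored-crop decoding), temporal identity association via
    optical-flow-shifted cost matching, appearance-based identity
    assignment, and accuracy evaluation (object keypoint similarity,
    PoseTrack-style mAP/mAR, localization-error distributions and identity
    switches). A seeded synthetic scene and session generator stands in for
    cameras and trained networks so the whole pipeline is testable at desk
    scale. Labeled datasets are stored in a single portable HDF5 container.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rhdf5,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
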