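Package: rotapose
Title: Rotating-Platform Posture Photogrammetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative body-posture evaluation from video frames of a
    subject standing on a slowly rotating platform. Provides pixel-to-
    centimetre calibration from fiducial marks on a calibration support,
    landmark-based posture metrics (spinal curvature index, distances,
    angles, polygon areas), multi-frame aggregation with accumulated
    coefficient-of-variation statistics and a repetitions-needed
    stabilization rule that decides how many near-identical frames must be
    averaged to control parallax error, and a pinhole-camera turntable
    simulator for validating the frame-averaging strategy against known
    geometry. Includes the published 30-frame validation measurements of a
    25 cm x 15 cm rectangle as a benchmark fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
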