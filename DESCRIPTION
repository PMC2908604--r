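Package: girdlekin
Title: Six-Degree-of-Freedom Pectoral Girdle Kinematics from Biplane X-Ray
    Motion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for marker-free biplane x-ray motion analysis of the
    mammalian pectoral girdle: hierarchical anatomical coordinate systems and
    rigid-body forward kinematics for a digital marionette (thoracic
    vertebra, scapula, humerus, clavicle), 11-parameter direct linear
    transformation (DLT) calibration with grid-based distortion correction
    and two-view 3D reconstruction, stride segmentation with speed and
    symmetry filters, 50+50-point gait-cycle time normalization and pooling
    into mean curves, virtual experiments that mute selected degrees of
    freedom to quantify the displacing effect of individual skeletal
    elements on the elbow trajectory, and pectoral-girdle morphometrics.
    Includes a seeded synthetic-data generator emulating suspensory
    quadrupedal stride kinematics for testing every stage without recorded
    radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
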