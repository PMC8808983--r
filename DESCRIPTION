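Package: pelvir
Title: Pelvic Incidence Measurement Under Pelvic Rotation from 3D Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the radiographic measurement of pelvic
    incidence (PI) changes when the pelvis is rotated relative to the
    sagittal viewing plane. Provides a synthetic pelvis generator that
    emulates CT-segmented femoral heads and the S1 endplate as labeled 3D
    point clouds with known anatomical PI, least-squares sphere, three-point
    circle and principal-axis endplate fitting, orthographic projection onto
    viewing planes rotated about the vertical or horizontal reference axis,
    2D PI measurement with a closed-form analytic oracle, rotation sweeps
    with a 6-degree acceptability criterion, cohort aggregation, and
    ICC(3,1) reliability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
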