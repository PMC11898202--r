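Package: earpair
Title: Ear-Root Pairing and Body-Temperature Extraction from Thermal
    Images of Group-Housed Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-contact body-temperature measurement of
    group-housed pigs from 8-bit thermal images. Implements a two-stage
    algorithm that pairs left and right ear-root oriented bounding boxes
    belonging to the same pig: a rough stage that greedily matches boxes
    by minimum center distance within a fixed pixel window, and a precise
    stage that validates each pair by classifying the boxes as left or
    right ear from the polar angles of their centers about the
    intersection of the pair's outermost lines, dissolving and re-pairing
    inconsistent matches. Includes oriented-box geometry (rotated IoU,
    rasterization, vertex selection), readers and writers for YOLO-OBB
    text labels and roLabelImg XML, linear grayscale-to-temperature
    mapping with per-frame temperature metadata, per-pig temperature
    extraction, detection and pairing evaluation metrics, measurement
    agreement analysis, and a seeded synthetic scene generator with full
    ground truth so every stage is testable without a camera or a
    trained detector.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
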