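Package: fruittrack
Title: Multi-Class BYTE Tracking and ROI-Band Counting for Fruit
    Inspection Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detector-agnostic toolkit for classifying and counting
    fruit-stage targets (flowers, green fruit, red fruit) in inspection
    video detection streams. Implements a class-augmented constant-velocity
    Kalman filter, two-stage confidence-partitioned (BYTE) data
    association with a 30-frame lost-track buffer, region-of-interest
    band counting with per-class counted-ID lists, the full
    detection- and counting-evaluation metric suite (precision, recall,
    average precision, counting accuracy Pc/APc/mAPc), readers and
    writers for MOT-style CSV and YOLO-style text detection files, and a
    synthetic inspection-scene simulator that stands in for video plus a
    trained detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    vctrs,
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
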