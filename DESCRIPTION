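Package: farrowwatch
Title: Early Warning and Supervision of Sow Farrowing from Detection Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detector-agnostic pipeline for predicting and supervising sow
    farrowing from time-stamped object-detection streams (four sow postures
    plus newborn piglets). Computes the posture-transition frequency
    statistic on a sliding window, issues pre-farrowing warnings via a
    dual-threshold persistence rule (upper 17.5/h, lower 10/h, sustained
    more than 5 h), raises a debounced farrowing alarm on consecutive
    newborn-piglet detections, counts piglets, and evaluates results with
    current/detected-number accuracy, precision/recall, and GIoU/BCE
    reference losses. Includes a stochastic simulator of perinatal sow
    behavior and of detector noise so the whole pipeline is testable
    without video, plus readers for JSON-Lines detection streams and
    PASCAL VOC XML annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
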