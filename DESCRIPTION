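Package: flockwatch
Title: Differential Motion Detection and Flock-Triggered Deterrence for
    Vineyard Bird Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A software pipeline for camera-based protection of fruit crops
    from bird flocks. Detects moving objects in grayscale frame sequences by
    frame differencing with an accumulated-background filter that suppresses
    quivering vegetation, extracts candidate bounding boxes from binary
    masks, classifies candidates (bird, bug, flock, helicopter) through a
    pluggable classifier contract with a reference heuristic, groups five or
    more nearby birds into flocks, scores detections against ground-truth
    annotations (IoU matching, precision, recall, F1, error rate, confusion
    matrix), emits actuator trigger events only for flocks above a
    confidence threshold, plans 360-degree camera coverage from the
    horizontal field of view, and generates seeded synthetic vineyard scenes
    with ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
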