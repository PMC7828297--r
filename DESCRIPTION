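Package: cornstand
Title: Corn Seedling Stand Counting by Tracking-by-Detection
Version: 0.1.0
Authors@R: person("Stand Count", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Counts corn seedlings in video-style detection streams using a
    constant-velocity Kalman filter over bounding-box center, area and aspect
    ratio, optimal IoU-gated assignment of detections to tracks, a max-age
    track lifecycle, and a finish-line crossing counter. Includes a seeded
    synthetic scene simulator emulating a row-following camera cart with
    detector failure modes (misses, short-lived false positives, split
    detections, aspect-ratio flutter), detection-file input/output in an
    MOT-style text format, and evaluation metrics (counting accuracy,
    TP/FP/FN matching, average precision at a fixed IoU threshold).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
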