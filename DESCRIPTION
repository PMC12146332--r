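Package: germtrack
Title: Germination Time-Lapse Quantification for Seed Imagery
Version: 0.1.0
Authors@R:
    person("germtrack", "developers", email = "germtrack@example.org",
           role = c("aut", "cre"))
Description: Measurement pipeline for seed germination time-lapse imagery:
    Pascal VOC annotation input/output with a deterministic 7:2:1 dataset
    split, salt-and-pepper noise augmentation, a synthetic germination
    time-lapse generator with analytic ground truth, threshold binarization
    and white-pixel morphometry of annotated seed crops, multi-family
    growth-curve regression with R-squared model selection and
    derivative-based germination-potential curves, and object-detection
    evaluation metrics (IoU matching, precision/recall, AP, mAP, germination
    rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2
Suggests:
    jpeg,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
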