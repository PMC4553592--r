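Package: beeshimmer
Title: Quantification of Flickering and Shimmering in Giant Honey Bee Nest Videos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Frame-difference motion analysis of Giant Honey Bee (Apis
    dorsata) nest-surface videos. Converts grayscale frame stacks into
    per-pixel difference images and bee-sized test-square luminance-change
    (dlum) time series, detects brief abdomen-flipping ("flickering")
    transients with a run-length interval filter, masks shimmering-wave
    episodes, pools shimmering-wave trigger sites into scaled activity maps
    and a trigger/non-trigger square partition, and compares the cohorts'
    flickering rate and intensity with binned exponential regressions,
    Spearman correlation, and a sign/chi-square test. Ships a synthetic
    nest-video generator with exact ground truth so every stage is testable
    without field footage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
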