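Package: footprintr
Title: Footprint Morphometrics, Body-Mass Estimation and Trackway Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of human and fossil hominin
    footprints. Orients 3-D footprint surfaces to a best-fit plane through the
    undisturbed surrounding sediment and measures impression depths at 14
    functionally relevant anatomical landmarks; estimates body mass from five
    external print dimensions with a bagged regression-tree ensemble,
    benchmarked against a length-only linear regression; classifies walking
    versus running prints; tests whether a trackway's mean depth topography
    lies within the range of modern human variation using a subject-level
    resampling Mahalanobis null distribution; and attributes sex to trackways
    by the mean method. Includes a synthetic footprint generator with known
    ground truth for calibration and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    pracma,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
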