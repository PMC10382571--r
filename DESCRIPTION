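Package: dotmatch
Title: Spatial Agreement Statistics for Dot-Matching Correspondence
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for dot-matching (landmark correspondence)
    psychophysics experiments. Quantifies inter-observer spatial agreement
    per probe location as the mean pairwise distance between placed dots,
    compares it against a uniform-within-contour resampling null and a
    conservative neighbor-probe reference, and tests condition and cohort
    differences (median-proximity, response-time, Likert and identity
    judgements) with paired and two-sample t-tests. Includes planar
    geometry primitives (point-in-polygon containment, uniform rejection
    sampling inside simple polygons, componentwise and geometric medians),
    CSV/GeoJSON data model and validation, a synthetic observer simulator
    with known ground truth for power and type-I calibration, and a
    simulate/analyze/report command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
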