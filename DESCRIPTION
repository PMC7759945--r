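Package: dielcam
Title: Diel Activity Patterns and Spatial Co-Occurrence from Camera-Trap
    Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing time-stamped camera-trap detections of
    terrestrial mammals: filtering of independent detection events,
    classification of diel activity (diurnal, nocturnal, crepuscular,
    cathemeral), circular kernel density estimation of activity patterns
    with von Mises kernels, non-negative trigonometric-sum densities,
    the Hermans-Rasson test of circular uniformity, activity-level
    estimation, pairwise temporal-overlap coefficients (Dhat1/Dhat4)
    with bootstrap confidence intervals, a probabilistic (hypergeometric)
    model of pairwise spatial co-occurrence over camera stations, and a
    Mantel test relating temporal overlap to spatial association.
    Includes a synthetic detection-data generator that emulates a
    multi-site camera-trap survey of an African forest duiker community,
    so the full pipeline can be exercised end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
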