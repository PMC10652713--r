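Package: bodymaps
Title: Case-Control Analysis of Bodily Sensation Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for case-control studies of bodily sensation maps
    (participant-coloured human silhouettes of emotion, pain and tactile,
    nociceptive and hedonic sensitivity). Provides procedural silhouette
    masks with an eight-region anatomical atlas, a calibrated synthetic
    cohort generator with spatially structured (blob) colouring, colouring
    preprocessing with quality control and empty-body semantics, greedy
    age- and gender-matched control selection, mass-univariate pixel-wise
    two-sample t and two-proportion z maps with Benjamini-Hochberg false
    discovery rate thresholding over the silhouette, region-of-interest
    extent summaries, a robust between-by-within ANOVA on trimmed means
    with winsorized covariances (Johansen-type approximation),
    Mann-Whitney tests with exact enumeration, Fisher r-to-z contrasts of
    independent correlations, and an end-to-end pipeline with rendered
    map figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
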