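Package: saltatr
Title: Quantitative Analysis of Saltatory Cell Migration Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the migratory behaviour of cells from
    2D time-lapse tracks, designed around the saltatory (run-and-pause)
    locomotion of migrating neurons. Computes a 48-descriptor feature
    vector per track, partitions tracks into dwell states and moving
    tracklets by spatiotemporal density-based clustering, locates major
    directional changes by Ramer-Douglas-Peucker simplification, derives
    mean-squared-displacement and velocity-autocorrelation curves,
    clusters tracks into migration modes anchored on a control group
    (z-score, PCA, K-means), and screens per-feature treatment effects
    with Kruskal-Wallis and Mann-Whitney U tests under Bonferroni
    correction. Includes a motion-model simulator (ballistic, random
    walk, persistent walk, saltatory, confined, stationary) so every
    stage is testable against planted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
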