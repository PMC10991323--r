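Package: anttrail
Title: Automated Analysis of Ant Trail-Following Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying trail-following behaviour of individual
    ants in video-recorded arena assays. Provides spatio-temporal video
    binning, background-subtraction segmentation and gap-tolerant single-ant
    tracking, the on-trail walked-distance metric based on point-to-segment
    geometry with a 5 mm classification rule, group occupancy heatmaps, and
    the group-level statistical battery (ln(y+1) transform, one-way ANOVA,
    Dunnett many-to-one comparisons against a control, pairwise t-tests).
    Includes a seeded synthetic-data generator (correlated random walks with
    tunable trail attraction, rendered grayscale frames, and group-level
    walking-distance tables) that supplies ground truth for every pipeline
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    png,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    tidyr,
    multcomp,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
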