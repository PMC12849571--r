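Package: kinectome
Title: Whole-Body Inter-Segmental Gait Coordination Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds kinectomes -- symmetric matrices of pairwise Pearson
    correlations between body-segment acceleration time series over single
    gait acquisitions -- from optical motion-capture marker trajectories,
    and compares them between groups. Includes a synthetic gait generator
    with controllable inter-segment coordination structure, a BIDS-like
    tabular marker reader and writer, gait-cycle segmentation from heel
    trajectories, greedy maximum-weight path-pattern extraction on the
    complete coordination graph, and group-level permutation, bootstrap
    and pattern statistics with Bonferroni adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    igraph,
    signal,
    pracma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    readr,
    ggplot2
Config/testthat/edition: 3
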