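Package: redunet
Title: Functional Redundancy Analysis of Brain Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs density-thresholded binary functional connectivity
    graphs from regional fMRI time series, computes path/walk redundancy
    (direct plus indirect routes up to a maximum length), degree and global
    efficiency, and runs the associated inferential pipeline: permutation
    ANCOVA group comparisons with Benjamini-Hochberg-corrected post hocs and
    Cohen's d, nodal redundancy ratio sets tested against a random-node-pair
    null, and cognition/efficiency regressions with ordinary and
    Huber-robust fits. Includes a synthetic-cohort generator emulating a
    three-group (cognitively normal, early and late mild cognitive
    impairment) resting-state study design so every stage is testable
    without access to clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
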