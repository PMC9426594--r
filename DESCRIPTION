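Package: sgarray
Title: Synthetic Genetic Array Analysis of High-Density Colony Fitness Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring genetic interactions from synthetic genetic
    array (SGA) colony screens of double-deletion strain collections.
    Provides a seeded simulator of high-density (384/1,536) colony arrays
    with planted fitness structure, plate normalization with per-ring
    edge-effect correction and leave-strain-out interquartile-mean scaling,
    multiplicative-rule interaction scoring with propagation-of-errors
    uncertainty, Welch tests with Benjamini-Hochberg false-discovery-rate
    control, interaction tallies and deviation histograms, interaction
    network construction with Louvain communities and force-directed
    layouts, growth-curve feature extraction (maximum amplitude and
    first-order growth rate), and genome-scale phenocopy and suppressor
    screen analytics.
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
    graphics,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
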