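Package: mesobreak
Title: Range-Edge Breakpoint Analysis of Mesopredator Suppression from
    Bounty Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to test the Enemy Constraint Hypothesis with
    per-hunting-unit predator bounty records. The pipeline turns bounty
    counts at unit centroids into a weighted bivariate Gaussian kernel
    density surface for the top predator, extracts the 85% volume
    isopleth as the range edge, computes signed distances from every
    hunting unit to that edge (negative outside the range), and fits
    continuous one-breakpoint piecewise linear regressions of z-scored
    abundance indices on signed distance with bootstrap confidence
    intervals, a slope-change test and spatial residual diagnostics
    (including a permutation Moran's I). A synthetic landscape generator
    with known ground truth makes every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tibble,
    rlang,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
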