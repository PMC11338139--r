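Package: swcorr
Title: Sliding-Window Correlation Analysis of Driver-Response Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coupled analysis of a driving variable and a response variable
    with correlation and partial-correlation coefficients computed inside
    overlapping value-range windows of the driver. The windowed coefficient
    acts as an order parameter whose loss of significance or change of sign
    locates regime transitions, yielding input-intensity thresholds such as
    the fertilizer level beyond which yield gains stall. Includes min-max
    normalization to a 0-100 scale with exact inverse transforms, a
    four-level significance stratification, a synthetic generator for
    piecewise-coupled systems with confounders, CSV export of per-window
    results, significance-colored diagnostic plots, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
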