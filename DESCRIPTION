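Package: growplate
Title: Tidy, Preprocess, Fit and Summarize Microtiter-Plate Growth Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for high-throughput microbial growth-curve
    analysis. Reads heterogeneous plate-reader measures files (long and wide
    CSV, a Bioscreen-style wide dialect) and experiment design files (generic
    CSV and plate-shaped 'plater'-style layouts) into one canonical tidy
    table; applies a six-step preprocessing chain (log-ratio transform,
    running-median and running-mean smoothing, monotone-increasing
    enforcement, and formula-driven background correction and calibration);
    fits smoothing splines, reparameterized Gompertz, logistic and Richards
    sigmoid growth models, or arbitrary user-specified models via a safe
    formula mini-language; extracts per-well summary metrics (maximum value,
    maximum slope and its tangent intercepts, area under the curve, asymptote
    A, maximum growth rate mu, lag time lambda, minimum doubling time) and
    fit-quality statistics; groups wells into reference and target sets with
    a compact shorthand grammar; and exports tidy CSV results. A seeded
    simulator generates realistic multi-run, multi-plate experiments in every
    supported file dialect for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
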