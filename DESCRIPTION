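Package: gccd
Title: Graph-Constrained Changepoint Detection for R-Peak Detection in ECG
    Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects R-peaks in raw electrocardiogram (ECG) signals by
    solving a penalized, graph-constrained changepoint detection problem
    exactly with a functional-pruning dynamic program over piecewise
    quadratic cost functions. A directed constraint graph encodes the
    expected sequence of hidden states in a cardiac cycle together with the
    direction, minimum amplitude gap, and penalty of each transition; the
    solver recovers the globally optimal segmentation (changepoints, states
    and segment means) without any signal preprocessing. The package also
    provides a greedy graph-structure learning algorithm driven by weakly
    labeled peak regions, beat-matching evaluation metrics (sensitivity,
    positive predictivity, detection error rate), synthetic signal
    generators (constraint-graph walks and ECG-like beat trains with known
    ground truth), CSV/JSON interchange, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    readr,
    ggplot2,
    generics,
    withr,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
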