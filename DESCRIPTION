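Package: dtwmedoids
Title: Incremental Fuzzy C-Medoids Clustering of Time Series Under Dynamic Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted fuzzy c-medoids clustering of univariate time series
    with a Dynamic Time Warping (DTW) distance, including single-pass and
    online drivers that process large datasets chunk by chunk while carrying
    weighted medoids between chunks. Provides an exact DTW kernel with
    warping-path backtracking, a reader/writer for UCR-archive style
    delimited time-series files, external cluster-validity statistics
    (F-Measure, entropy, hypergeometric enrichment p-values and a clustering
    score), and a seeded generator of labelled synthetic series with random
    monotone time warps for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
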