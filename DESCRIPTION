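Package: msetest
Title: Exact Statistical Test and Scalable Visualization of Multi-Set
    Intersections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact one-tailed significance tests for the intersection of two or
    more sets drawn independently from a finite background population. The
    distribution of the multi-set intersection size is computed with a
    forward (dynamic-programming) factorization of the nested hypergeometric
    sums, carried out entirely in log space so that tail probabilities far
    below the double-precision underflow floor remain representable. The
    package enumerates all set combinations with fold-enrichment statistics
    and multiple-testing adjustment, provides matrix (UpSet-style), circular,
    heatmap and network visualizations, a weighted-sampling simulator for
    assessing type-I-error behaviour under biased sampling, and readers for
    GMT and column-per-set files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
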