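Package: cinet
Title: Functional Network Analysis of Calcium Imaging Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of pre-extracted calcium-imaging fluorescence
    traces: per-cell min-max or z-score normalization, threshold binarization
    into event rasters, population-activity summaries (active-cell percentage,
    events per minute, Ward-clustered rasters), lagged cross-correlation
    functional connectivity, thresholded weighted network construction with
    graph-theoretic characterization (degree, clustering coefficient, global
    efficiency, leading-eigenvector community detection), labeled-subset
    interaction analysis, principal component analysis and Welch power
    spectral density estimation, unified behind a single deterministic
    pipeline with a tabular summary report and figure generation. Includes a
    seedable synthetic-population generator with planted assemblies and a
    labeled subset for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    rlang,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
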