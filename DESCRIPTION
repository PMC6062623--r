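Package: netreconfig
Title: Dynamic Reconfiguration Analysis of Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying condition-dependent reconfiguration of functional
    brain networks from region-of-interest (ROI) time series. Provides a synthetic
    multi-subject generator with planted two-state modular covariance and connector
    hubs, discrete-cosine high-pass filtering and component-based (CompCor-style)
    nuisance regression, condition-binned Fisher-z connectivity via HRF-weighted
    correlation, proportional density thresholding, leading-eigenvector spectral
    modularity with Kernighan-Lin refinement, global/local efficiency, flow and
    participation coefficients, betweenness centrality, density-sweep paired
    contrasts with pooled summary statistics, and ROI-level generalized
    psychophysiological interaction (gPPI) modelling with FDR or sign-flip
    permutation group inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    mclust,
    jsonlite
Config/testthat/edition: 3
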