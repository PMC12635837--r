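Package: connectocore
Title: Core-Periphery and Degree-Distribution Analysis of Directed Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing directed synaptic wiring diagrams
    (connectomes) through their core-periphery organisation. Implements
    D-core decomposition of directed graphs with frontier-core extraction,
    directed rich-club coefficients normalised against degree-preserving
    random surrogates, maximum-likelihood fitting of discrete Weibull
    (stretched-exponential) and power-law degree distributions with
    Kolmogorov-Smirnov x_min selection, neighbourhood cell-type composition
    and diversity indices, type-wise connection-probability matrices,
    consensus Louvain community detection with directed modularity,
    targeted-attack robustness summaries, and a synthetic planted-core
    connectome generator for validation without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
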