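Package: megnet
Title: Source-Space MEG Connectivity Networks and Permutation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A resting-state magnetoencephalography (MEG) source-connectivity
    pipeline: multitaper cross-spectral density estimation with discrete
    prolate spheroidal sequence (DPSS) tapers, Dynamic Imaging of Coherent
    Sources (DICS) beamforming on a regular volumetric grid with a spherical
    head model, functional connectivity via the absolute imaginary part of
    coherency, weighted graph measures (nodal strength, Onnela clustering,
    characteristic path length) with surrogate normalization, and
    nonparametric group inference (spatial cluster-based permutation tests,
    the network-based statistic, FDR-corrected regional tests). Includes a
    forward-model-consistent synthetic cohort generator with planted,
    band-limited, phase-lagged coupling effects so every stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
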