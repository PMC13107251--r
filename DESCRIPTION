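Package: layerlight
Title: Dual-Slope Frequency-Domain NIRS in Layered Head Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward modeling and analysis of dual-slope (DS) frequency-domain
    near-infrared spectroscopy (FD-NIRS) measurements on layered head-mimicking
    media. Provides a zero-absorption ("white") Monte Carlo photon transport
    kernel that records per-layer path lengths for every detected photon, so
    complex reflectance and its per-layer absorption derivatives can be
    assembled for any absorption set by exact exponential re-weighting; the
    analytic semi-infinite diffusion model with extrapolated boundary
    conditions; the six DS FD-NIRS data types and the self-calibrated fit of
    effective homogeneous optical properties from dual-slope baseline data;
    retrieval of effective absorption changes and hemoglobin concentration
    changes; a three-layer sensitivity-matrix inversion separating superficial
    from cerebral absorption changes; and a block-protocol functional pipeline
    (folding average, smoothing, 3-sigma peak detection) together with a
    synthetic functional time-series generator for testing it.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
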