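Package: tractnet
Title: Structural Brain-Network Analysis from Diffusion Tractography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds weighted structural connectomes from diffusion tensor
    imaging and deterministic streamline tractography, computes global
    graph-theoretic measures of network segregation (clustering, modularity)
    and integration (characteristic path length, global efficiency) with
    degree-preserving null-model normalization and small-worldness, and
    tests group differences and glycemia-network associations with
    permutation tests, Benjamini-Hochberg false-discovery-rate control and
    covariate-adjusted partial correlations. Includes a calibrated
    synthetic-cohort generator and tensor phantoms so the full pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    stats,
    withr,
    yaml,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    MASS
Config/testthat/edition: 3
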