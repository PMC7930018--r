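Package: mcdock
Title: Multicanonical Dynamic-Docking Analysis on Coarse-Grained Binding Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multicanonical molecular dynamics (McMD)
    based dynamic docking: iterative flat-histogram bias estimation and
    canonical reweighting, free-energy landscapes over distance-pair principal
    components, cluster free-energy ranking with contact-based similarity
    metrics (Q-value, R-value, RMSD variants, relative accessible surface
    area), binding-path construction along an estimated unbinding direction,
    and umbrella sampling with weighted-histogram (WHAM) affinity estimation
    including standard-state volume corrections.  Ships a coarse-grained
    cryptic-site toy binding system with a Langevin integrator so the whole
    pipeline can be exercised end-to-end at desk scale against exact
    quadrature oracles.
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
    ggplot2,
    rlang,
    generics,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
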