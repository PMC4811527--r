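Package: ductsim
Title: Agent-Based Simulation of Mammary Ductal Epithelium and Carcinogenesis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time, stochastic, multi-cell-type agent-based model of
    the mammary ductal epithelium. Luminal, myoepithelial and fibroblast
    compartments interact through a cyclic hormonal environment and a
    paracrine signalling network (estrogen, amphiregulin, HGF, TGF-beta).
    Cells carry a twelve-gene functional genome under a two-hit copy-number
    model; heritable mutations arise from stochastic DNA damage/repair and
    replication errors, and transform normal hormone-driven tissue dynamics
    into hyperplastic and malignant states. Includes cohort-level virtual
    epidemiology: incidence with confidence intervals, ER/HER-2 receptor
    subtyping, early-mutation sequencing and mutation-burden comparisons,
    plus a calibration harness and plotting/tidying methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
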