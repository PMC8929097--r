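Package: acatpk
Title: Compartmental Absorption and Transit Modelling of Oral Drug
    Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of oral drug absorption with a
    compartmental absorption and transit (CAT/ACAT-style) gut model coupled
    to one-compartment systemic disposition, together with Caco-2 transwell
    apparent-permeability estimation and noncompartmental summary statistics
    (Cmax, Tmax, AUC, terminal slope, accumulation index). Ships a worked
    gemcitabine case study comparing intravenous infusion with five
    immediate-release tablet regimens, a synthetic transwell-assay generator
    for parameter-recovery validation, and tidy (tibble-based) interfaces
    with ggplot2 plotting throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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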