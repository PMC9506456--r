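Package: cumrisk
Title: Cumulative Dietary Risk Assessment of Pesticide Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic cumulative dietary risk assessment of
    pesticide mixtures sharing a common toxic effect. Summarizes supervised
    residue field trials into median (STMR) and highest (HR) residues with
    censored-value handling and maximum-residue-limit screening, fits
    first-order dissipation kinetics, computes analytical method-validation
    statistics (matrix effect, recovery, RSD), collapses multi-compound
    residues into index-compound equivalents with relative potency factors
    (RPF), and runs a nested two-dimensional Monte Carlo simulation of
    chronic dietary exposure separating population variability from
    parameter uncertainty, with risk characterization against NOAEL-based
    reference doses and contribution analysis by compound and food category.
    Includes a synthetic-data generator for residue trials and stratified
    consumption surveys with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
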