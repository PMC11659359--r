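Package: emtsens
Title: Sensitivity Analysis of a Bistable E-cadherin/Slug Model of the
    Epithelial-Mesenchymal Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a two-variable Hill-type ordinary differential equation
    model of membrane-bound E-cadherin and the transcription factor Slug during
    the epithelial-mesenchymal transition, driven by cell-cell contact and
    TGF-beta. Provides the dimensional model and its seven admissible
    nondimensionalizations, time-course integration to steady state,
    equilibrium enumeration with stability classification, saddle-node (fold)
    location and switch classification (reversible versus irreversible
    hysteresis), Latin hypercube sampling over tabulated parameter ranges,
    partial rank correlation coefficient (PRCC) sensitivity analysis with
    inter-parameter screening and monotonicity diagnostics, and an
    orchestrated study comparing which parameters are flagged significant
    under the dimensional model and each nondimensional variant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
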