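Package: rmdyn
Title: Regulatory Dynamics of C-Controlled Restriction-Modification Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Biophysical modelling of Type II restriction-modification (R-M)
    systems controlled by a dedicated C protein. Implements a statistical-weight
    (thermodynamic) model of the C/R operon promoter with full monomer-dimer
    equilibrium, analytic saddle-node (fold) boundaries and cusp-point location
    in the leakage/expression-strength plane, bifurcation diagrams and cusp
    catastrophe surfaces, steady-state methyltransferase models for three
    promoter architectures (Esp1396I, AhdI, EcoRV) with M-to-R ratio curves,
    least-squares inference of promoter leakage from activity curves, expression
    time series and steady-state-versus-copy-number data, and exact stochastic
    simulation of single-cell dynamics with binomial partitioning at cell
    division (constitutive, regulated and post-segregational modes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
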