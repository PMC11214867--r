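Package: atmkit
Title: Desk-Scale Alchemical Transfer Free Energy Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relative binding free energy (RBFE) machinery built around the
    Alchemical Transfer Method (ATM) at desk scale: seeded toy host-guest
    systems with closed-form transfer free energies, a molecular-mechanics
    energy model with an optional smooth surrogate intramolecular potential
    (an NNP/MM-style hybrid decomposition), soft-core capped softplus
    alchemical coupling, BAOAB Langevin dynamics with Hamiltonian replica
    exchange over lambda windows, UWHAM multistate free energy estimation
    with asymptotic uncertainties, maximum-likelihood reconstruction of
    absolute binding free energies from a perturbation network, and a
    benchmark statistics layer (MAE, RMSE, Kendall tau, bootstrap errors,
    accuracy-threshold fractions) with table and plot output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
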