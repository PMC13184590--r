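Package: pahfire
Title: Wildfire Contributions to Atmospheric PAH Concentrations and Cancer Risk
Version: 0.1.0
Authors@R:
    person("pahfire", "maintainers", email = "pahfire@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for quantifying the wildfire contribution to
    polycyclic aromatic hydrocarbon (PAH) air pollution and the associated
    incremental lifetime cancer risk (ILCR). Provides a registry of the 16 EPA
    priority PAHs plus nitro- and dinitro-PAH degradation products, fire-sector
    emission speciation redistribution, a simplified gridded per-cell fate model
    (ppLFER gas-particle partitioning, first-order oxidative losses, degradation
    product diagnosis), baseline versus no-wildfire scenario attribution,
    toxic-equivalency health-risk metrics (ILCR, toxicity per unit mass),
    model-observation evaluation by normalized mean bias, a seeded synthetic-data
    generator, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
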