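Package: levansim
Title: Dynamic Metabolic Modelling of Levan Production by Bacillus subtilis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid dynamic-constraint-based modelling of batch levan
    fermentation by levansucrase-secreting Bacillus subtilis. A kinetic
    ordinary differential equation model describes biomass growth (Monod),
    sucrose uptake, and the three levansucrase-mediated reactions
    (hydrolysis, transfructosylation, levan degradation) with a Heaviside
    onset for degradation. The model is calibrated to observed fermentation
    time courses by bounded least squares with NRMSE validation, summarised
    into production metrics, and coupled at a time snapshot to a
    stoichiometric metabolic network via growth, sucrose-uptake and
    enzyme-yield constraints. Intracellular fluxes are estimated by
    minimal-total-flux (parsimonious) flux balance analysis, with flux-sum
    turnover analysis, reaction activity classification across sucrose
    regimes, and in silico enhancement scenarios (enzyme-yield modulation,
    amino-acid supplementation, reaction knockdown).
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
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
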