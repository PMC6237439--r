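Package: syngut
Title: Kinetic Modeling of a Three-Strain Synthetic Gut Community
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic Monod-kinetics modeling of batch co-cultures of
    three human gut isolates (Roseburia intestinalis L1-82, Faecalibacterium
    prausnitzii A2-165 and Blautia hydrogenotrophica S5a33) that compete for
    fructose and cross-feed formate and acetate. Provides the coupled ODE
    system for strain abundances, lag-phase state variables and seven
    metabolites; adaptive integration and trajectory summaries; staged
    parameter estimation against fermentation time series via normalized
    RMSE and derivative-free optimization; fermentation carbon-recovery and
    oxidation/reduction balances; dominance scans over initial abundances
    and lag phases; and a seeded synthetic-data generator emulating
    qPCR/HPLC batch fermentation tables for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
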