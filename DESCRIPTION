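Package: sednitro
Title: Nitrogen Cycling in Oligotrophic Deep-Sea Sediments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative tools for microbial nitrogen cycling in deep,
    oxygenated, organic-poor marine sediment columns that receive oxygen both
    from the overlying seawater and from an underlying oxic basaltic aquifer.
    Implements a one-dimensional steady-state reaction-transport model with
    six species (organic matter, O2, NO3-, NH4+, Mn2+, MnO2) and five
    reactions (aerobic respiration, heterotrophic denitrification, manganese
    reduction, nitrification, Mn2+ oxidation), Fick's-law diffusive flux
    budgets, detection of oxic-anoxic and anoxic-oxic transition zones,
    conversion of volumetric reaction rates and functional-gene abundances
    into cell-specific metabolic rates and biomass turnover times, community
    statistics (rarefied richness, functional-group abundances, and a
    surface-community reappearance statistic), and a synthetic-data generator
    with known ground truth for testing every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
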