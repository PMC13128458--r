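Package: ridgebudget
Title: Habitat and Standing-Stock Budgets for Sea-Ice Pressure Ridges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for budgeting biological habitat in deformed Arctic sea
    ice. Converts the physical state of ridge keels and level ice (keel
    depth, consolidation, rubble macroporosity, block geometry, drafts,
    areal coverage) into per-compartment unit volumes, and combines them
    with per-compartment chlorophyll-a and particulate organic carbon
    concentrations into areal standing stocks with first-order
    standard-error propagation. Includes brine volume fraction
    parameterizations (the Frankenstein-Garner closed form and the
    Cox-Weeks / Lepparanta-Manninen phase relations) with a permeability
    classification, measurement-level corrections (dried-filter
    chlorophyll, leucine-to-carbon conversion, biogenic and lithogenic
    silica time-course splitting), and a seeded synthetic-data generator
    for pipeline validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
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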