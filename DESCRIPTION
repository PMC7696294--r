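Package: dietopt
Title: Multi-Objective Distance-to-Target Design of Sustainable Diets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores daily diets on nutrition (the NRD9.3 nutrient-density
    index and its weighted variant), greenhouse-gas emissions, and cost;
    normalizes the three indicators and measures a weighted distance to an
    ideal target (full nutrient adequacy, zero emissions, zero cost); and
    optimizes food quantities under energy, adequacy, limiting-nutrient and
    acceptability constraints to minimize that distance. Includes
    epsilon-constraint Pareto fronts, Monte-Carlo sensitivity of the
    nutrient weighting, a corrected greenhouse-gas metric for cross-diet
    comparison, and a synthetic food-database generator for method studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nloptr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
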