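Package: reefpress
Title: Tide-Pool Reef Fish Assemblages, Feeding Pressure and Herbivore Selectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative pipeline for contrasting tide-pool reef habitats:
    allometric fish biomass from belt-transect visual censuses, a mass-scaled
    (bites x kg) feeding-pressure statistic from remote-video plots,
    point-intercept percent cover for photoquadrats and stomach spreads,
    control-corrected consumption and Strauss linear selectivity with bootstrap
    confidence intervals from multiple-choice herbivory assays, and natively
    implemented community statistics (Bray-Curtis dissimilarity, ANOSIM,
    principal coordinates and components analysis, Friedman rank tests).
    Includes a seeded synthetic-data generator that emulates the sampling
    designs so every stage is testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
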