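Package: dietimpact
Title: Diet Quality and Environmental Impact of Survey-Derived Dietary Patterns
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for household food-consumption surveys:
    converts household 24-hour food records to per-adult-female-equivalent
    (AFE) daily intakes via energy-requirement ratios, derives dietary
    patterns by principal component analysis of 18 food-group intakes,
    scores micronutrient adequacy with the probability approach (mean
    probability of adequacy, MPA, including a full-probability treatment of
    iron and an adequate-intake threshold for calcium), computes the
    Minimum Dietary Diversity for Women (MDD-W) score, links item-level
    greenhouse-gas and blue-water footprint factors, and reports every
    outcome by pattern-adherence quintile with homogeneity and linear-trend
    statistics. Ships a synthetic survey generator with planted latent
    dietary patterns so the whole pipeline is testable without access to
    restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
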