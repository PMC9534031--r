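Package: rhizoQG
Title: Quantitative Genetics of Half-Sib Legume-Rhizobium Symbiosis Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative-genetic analysis of half-sib family
    trials of plant growth under Rhizobium symbiosis, as run in controlled
    environment split-plot designs. Simulates trials with known
    variance-component truth, derives symbiotic potential and root:shoot
    traits from plant-level dry matter, fits the random-effects trial model
    by restricted maximum likelihood (REML) with best linear unbiased
    predictors (BLUPs) of family effects, and turns the fitted components
    into narrow-sense heritabilities, genetic and phenotypic correlations,
    predicted genetic gain under among-family selection, Smith-Hazel
    multi-trait selection indices, correlated responses to selection, and
    pattern analysis (Ward clustering with the Hartigan rule, and PCA
    biplot coordinates).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
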