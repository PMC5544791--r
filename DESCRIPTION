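Package: rivertraits
Title: Taxonomic and Functional Trait Analysis of Macroinvertebrate
    Communities Across River Biotopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for appraising in-channel habitat (biotope) and river
    restoration effects on benthic macroinvertebrate communities using both
    taxonomic and fuzzy-coded functional-trait compositions.  Implements the
    trait-processing chain from raw fuzzy-coded affinities to
    community-weighted trait profiles, Bray-Curtis dissimilarity with
    principal coordinates analysis, permutational multivariate analysis of
    variance with restricted (blocked) permutations, multivariate dispersion
    analysis, SIMPER dissimilarity decomposition, group-equalized indicator
    value analysis over biotope combinations, inverse Simpson diversity with
    ANOVA and Tukey HSD contrasts, rarity and exclusivity audits, and a
    synthetic-data generator with known location and dispersion effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
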