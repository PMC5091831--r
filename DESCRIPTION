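Package: isofeather
Title: Phylogenetic Mixed Models for Feather Stable Hydrogen Isotopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate-Normal phylogenetic mixed models for
    individual-level feather stable hydrogen isotope values (delta-2H_f) with
    multiple individuals per species, species-specific (heteroscedastic) or
    common residual variances, and Pagel's lambda as a multiplier on the
    off-diagonal of a tree-derived species correlation matrix. Provides
    maximum-likelihood fitting with profiled generalized-least-squares fixed
    effects, a data-cloning Markov chain Monte Carlo cross-check of the
    optimizer, AICc multimodel inference over a 32-candidate set, pre-model
    screening of molt-origin outliers, a year-by-species ANOVA, and a
    synthetic-data generator (pure-birth tree samples and isotope records)
    emulating a boreal songbird banding study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    car,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
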