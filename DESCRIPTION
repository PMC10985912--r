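Package: fbnet
Title: Cross-Kingdom Microbial Association Network Ensembles over
    Occurrence-Filter Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers fungal-bacterial co-occurrence association networks from
    paired amplicon sequence variant (ASV) count tables and compares them
    between sample conditions. Joint centred log-ratio transformed counts are
    fed to Meinshausen-Buhlmann neighborhood selection with StARS stability
    selection, repeated over a grid of per-kingdom occurrence-filter
    thresholds to yield a paired network ensemble. Includes community
    statistics (alpha diversity, Bray-Curtis PERMANOVA, per-phylum richness
    contrasts), uniform random-graph null models for edge-type and shared-
    association frequencies, consensus extraction of frequently recovered
    associations with genus-level summaries, binomial and Poisson generalized
    linear models of association sign and frequency, and a synthetic paired
    community generator with planted, condition-specific cross-kingdom
    associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
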