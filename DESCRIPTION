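Package: endemicity
Title: Parsimony Analysis of Endemicity, Constraint Envelopes, and
    Richness Regression for Freshwater Biogeography
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers biogeographical structure from species-by-area
    incidence data. Implements Parsimony Analysis of Endemicity (PAE)
    with Fitch parsimony over binary presence/absence characters,
    random-addition-sequence heuristic search with tree-bisection-
    reconnection (TBR) branch swapping, exhaustive search for small
    problems, and majority-rule consensus trees; the Boundary Sum of
    Squares (BSS) constraint-envelope randomization test for upper-limit
    relationships between species richness and environmental variables;
    multiple regression of per-area species richness on climatic and
    area covariates; and seeded synthetic-data generators (area
    cladograms with endemic species, species-area scaling, planted
    constraint envelopes) so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
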