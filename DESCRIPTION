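Package: mothnets
Title: Structure of Plant-Pollinator Networks with Nocturnal Moths
Version: 0.1.0
Authors@R:
    person("mothnets", "developers", email = "mothnets@example.org",
           role = c("aut", "cre"))
Description: Assembly and structural analysis of qualitative bipartite
    plant-pollinator networks that combine diurnal flower-visitation records
    with pollen-load evidence from light-trapped nocturnal moths. Implements
    the per-individual pollen-grain scoring rule for nocturnal interactions,
    fifteen structural descriptors (size, connectance, web asymmetry, NODF
    nestedness, Barber bipartite modularity via a multi-start label-propagation
    optimizer), fixed-fixed (curveball) null-model Z-tests, random
    primary-extinction robustness (R50), Chao 2 sampling completeness from
    session-structured incidence, a degree-rank test for preferential
    attachment, and a diurnal-undersampling resampling experiment that tests
    whether substituting nocturnal for diurnal interactions breaks the
    undersampling trend. Includes a synthetic-community generator (random,
    preferential-attachment and pollination-syndrome scenarios) so the whole
    pipeline can be exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
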