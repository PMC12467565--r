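Package: altifun
Title: Rhizosphere Microbial Communities and Ecosystem Multifunctionality
    Along Altitudinal Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for altitudinal-gradient studies of rhizosphere
    soil microbial communities and soil ecosystem multifunctionality. Computes
    alpha and beta diversity from OTU count tables, signed co-occurrence
    networks with topology reports, null-model partitioning of community
    assembly into five ecological processes (betaNTI and Raup-Crick on
    Bray-Curtis), min-max-standardized ecosystem function and
    multifunctionality indices, ecoenzymatic stoichiometry vector length and
    angle, ANOSIM, one-way ANOVA with LSD compact letter displays, redundancy
    analysis, and partial least squares path modeling. A synthetic-data module
    generates phylogenies, communities under known assembly regimes, planted
    co-occurrence modules, and function panels with known path structure, so
    every stage can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
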