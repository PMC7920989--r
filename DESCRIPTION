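Package: pbindesign
Title: Phage Cocktail Design from Phage-Bacteria Infection Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing phage cocktails from host-range matrices.
    Binary phage-bacteria infection networks are packed toward maximal
    nestedness with a heuristic sorter or a genetic algorithm, and the
    nestedness temperature (0-100) is scored against the isocline of perfect
    order, with null-model significance testing. Bipartite modularity
    (Barber's Qb) is maximised by label-propagation-seeded BRIM. The cocktail
    size estimator phi = floor(log2(b*T/f + 2)) combines the number of target
    bacteria, the packed temperature and the matrix fill; cocktail members are
    then chosen by Ward clustering of quantitative lysis profiles and
    exhaustive one-phage-per-cluster enumeration. Synthetic generators for
    nested, random, modular and clustered quantitative matrices support
    simulation studies, and a 35-study survey of published infection networks
    ships as a packaged dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
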