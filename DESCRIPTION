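Package: microsholl
Title: Plaque-Centric Radial Profiling of Microglia and Study Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification toolkit for microglial population dynamics around
    amyloid-beta plaques in 2-D histology fields. Implements a plaque-centric
    adaptation of Sholl analysis (concentric annuli grown from each plaque
    boundary with neighbour-contact, background-density and tissue-border
    stopping rules, and majority-area cell assignment), BrdU
    proliferation-index and population-turnover arithmetic, reporter-intensity
    versus distance-to-plaque correlation, percent-positive-area measurement,
    and the accompanying study statistics (2^-ddCt relative expression with a
    multi-gene normalization factor, LOD-censored immunoassay fold changes,
    tie-corrected Kendall tau-b, T-maze alternation scoring). A seeded
    synthetic-histology generator produces plaque and cell tables with the
    spatial structure the analyses assume, so every stage is testable without
    tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
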