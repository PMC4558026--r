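Package: slavstrata
Title: Population-Genetic and Lexicostatistical Structure of Balto-Slavic
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable toolkit for the joint population-genetic and
    lexicostatistical analysis of Balto-Slavic (or any comparably structured)
    populations: Nei standard genetic distances from haplogroup frequency
    tables with group-mean summaries, non-metric multidimensional scaling with
    Kruskal stress-1, hierarchical analysis of molecular variance (AMOVA) with
    Phi-statistics and permutation tests over a linguistic hierarchy, Mantel
    and partial Mantel tests among genetic, geographic and linguistic distance
    matrices, a group-level identity-by-descent segment-sharing statistic with
    resampling comparisons, and cognate-matrix lexicostatistics with
    glottochronological dating, neighbor-joining trees and a consensus
    collapse rule. Synthetic-data generators with known ground truth emulate
    every input class so the whole pipeline is testable without external data.
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
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vegan,
    yaml
Suggests:
    ade4,
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
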