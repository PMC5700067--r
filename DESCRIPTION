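Package: elnsim
Title: Agent-Based Simulation of Ectopic Lymph Node Assisted Anti-Tumor
    Immunity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An off-lattice agent-based model of the interplay between a
    growing tumor, trafficking immune cells, and an ectopic (tertiary)
    lymph node structure seeded by reticular fibroblast cells.  Antigen
    presenting cells and T cells perform biased random walks in continuous
    2-D space, activated stromal cells emit Gaussian chemokine fields, and
    tumor radius dynamics respond to the tumor-infiltrating lymphocyte
    count.  The package also ships a standardized chemotactic-index panel
    of 48 chemokines assayed on five resting lymphocyte populations,
    together with the chemotactic-index calculator, a summary-statistics
    t-test, and the responder classification rule used to summarise the
    panel.  Includes replicate sweep experiments over the number of
    stromal cells, trajectory averaging, peak detection and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
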