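Package: isocascade
Title: Generalized Isotopic-Labeling States, EMU Decomposition and
    Steady-State Labeling Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact representation of and conversion between isotopomer, cumomer,
    punctured-cumomer (Reed-Muller) and mass-fraction descriptions of arbitrarily
    heteronuclear moieties; decomposition of atom-mapped biochemical reaction
    networks into flux-weighted elementary metabolite unit (EMU) identity systems;
    assembly and solution of the steady-state labeling cascade; and measurement
    models for high- and low-resolution mass spectrometry and NMR splitting
    patterns.  Includes a brute-force isotopomer-balance simulator used as an
    independent cross-check of the cascade solver, and a seeded generator of
    random well-posed atom-mapped networks for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
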