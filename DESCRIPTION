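Package: fluogen
Title: Property-Conditioned Autoregressive Generation of Organic Fluorophores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing organic chromophores and fluorophores with
    target optical properties (absorption and emission peak positions and
    bandwidths, extinction coefficient, photoluminescence quantum yield and
    lifetime) in a given solvent. Molecules are represented as heavy-atom
    graphs and built autoregressively by add / connect / terminate actions;
    a conditional action-probability model is trained by teacher forcing on
    stochastic depth-first-search decompositions of training molecules.
    Includes the matching evaluation stack (validity, uniqueness, novelty,
    fraction of molecules meeting the target property windows, Stokes shift,
    Crippen-type log P, degree of conjugation, fingerprint-based chemical
    space maps, reference-set lookup), a synthetic surrogate property oracle
    for desk-scale experiments, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    igraph,
    withr,
    digest,
    generics,
    ChemmineR,
    ChemmineOB,
    Rtsne,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
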