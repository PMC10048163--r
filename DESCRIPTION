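Package: quadfam
Title: Discovery, Refinement and Classification of G-Quadruplex Sequence Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects putative G-quadruplex (G4) regions in DNA, clusters them by
    edit distance and alignment similarity, aligns each cluster, trains plan7
    profile hidden Markov models, iteratively tests and merges profiles into
    distinct sequence families, classifies query sequences by normalized Akaike
    weights over family models, and annotates families with a restricted
    quadruplex thermodynamic model (layer/linker folding energies, Boltzmann
    ensemble summaries and quadruplex dot-bracket strings). Includes a
    synthetic-data generator with known family truth for end-to-end validation.
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
    stringr,
    ggplot2,
    generics,
    jsonlite,
    cluster,
    mclust,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readr
Config/testthat/edition: 3
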