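Package: metallomer
Title: Inferring Relative Cellular Metallomes from Expressed Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the relative cellular metallome of a microorganism
    from its expressed proteome. Metal-cofactor stoichiometries are derived
    from template protein structures by coordination-sphere analysis,
    transferred to expressed proteins through confidence-filtered
    fold-recognition matches, and combined with label-free proteomics
    intensities to give an abundance-weighted per-metal profile. The profile
    can be compared with ICP-MS metal quotas via log-space correlation,
    strain ratios with propagated uncertainty, and per-protein differential
    expression. A coupled synthetic-data generator (structures, match tables,
    replicate intensity matrices, quota tables) with known ground truth makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
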