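Package: cappedpep
Title: Discovery and Targeted Detection of Capped Peptides from Secreted Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts "capped" peptides -- secreted-protein fragments bearing
    an N-terminal pyroglutamate and a C-terminal amide -- from curated
    secretome sequences by scanning for glycine-dibasic (G[K/R]R) amidation
    motifs with an upstream glutamine. Computes modified monoisotopic masses,
    charge-state m/z and b/y fragment ions, and exports multiple reaction
    monitoring (MRM) transition lists. Applies two-step targeted-detection
    rules (MS1 parent-ion matching at ppm tolerance, MRM signal-to-noise
    validation, MS/MS daughter-ion confirmation) and external standard-curve
    quantification to feature and chromatogram tables. Includes downstream
    peptidome statistics (amino-acid composition tests, flanking-residue
    profiles, perturbation fold changes, tissue-expression z-score heatmaps),
    pharmacology curve fits (four-parameter logistic dose-response and
    exponential decay half-life), cross-species conservation and similarity
    trees, and synthetic-data generators with known ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    ape,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
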