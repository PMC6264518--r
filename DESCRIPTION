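Package: ariscr
Title: Sequence Homology and Cross-Reactivity Risk for Allergen Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes pairwise protein sequence identity and similarity
    under an explicit amino-acid similarity-group model and summarises
    them as the A-RISC index (the average of identity and similarity),
    a single value interpreted as the fraction of residues able to
    support binding of a cross-reactive IgE antibody. Provides a
    four-tier cross-reactivity risk classification (high, medium-high,
    medium-low, low), per-family pair matrices built from a multiple
    sequence alignment or from internal global pairwise alignments,
    family-level summaries and cross-family rankings, triangular risk
    heatmaps and per-reference homology profiles, a generator of
    synthetic homolog families with exactly controlled identity and
    similarity structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
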