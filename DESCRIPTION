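Package: xlmapr
Title: Large-Scale Mapping of Cross-Linking Mass Spectrometry Results onto Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch validation of chemical cross-linking mass spectrometry (CXMS)
    identifications against existing protein structures. Parses cross-link tables
    (pLink2-style CSV or a generic TSV) and a FASTA sequence database, reads
    mmCIF structure files, aligns identified protein sequences to structure
    chains, computes Ca-Ca Euclidean distances for every cross-link of every
    protein-protein interaction (PPI) on every candidate structure, classifies
    links as satisfied or over-length per cross-linker, scores each
    PPI-structure pair with a bounded structural-dynamism score, and exports
    tab-separated result tables plus PyMOL visualization scripts. A synthetic
    scene generator builds toy structures with known geometry so the whole
    pipeline is testable offline.
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
    readr,
    rlang,
    Biostrings,
    bio3d,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
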