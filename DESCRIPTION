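Package: gatafam
Title: Genus-Wide Identification and Comparative Analysis of GATA
    Transcription-Factor Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genus-scale analysis of the GATA transcription-factor
    family from annotated genomes. Detects class-IV zinc-finger GATA domains
    (C-X(2-4)-C-X(17-20)-C-X(2)-C) in protein isoforms and types them by
    inter-cysteine spacing, classifies alternative-splicing forms
    (UTR-only, identical-protein, domain-loss), aligns domains on their
    cysteine anchors, builds neighbor-joining trees with bootstrap support,
    assigns subfamilies from anchor sequences and extracts multi-species
    gene clusters, profiles per-position amino-acid conservation, summarises
    family composition, chromosomal distribution and expression coherence,
    and ships a seeded synthetic-genome generator that plants ground truth
    for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
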