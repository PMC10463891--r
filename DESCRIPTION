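Package: annocurate
Title: RNA-Evidence-Driven Curation and Evaluation of Gene Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automates the decision logic used to curate protein-coding gene
    models against RNA-seq evidence: detection of gene splits, gene fusions,
    intron-chain errors, de novo genes, alternative isoforms and UTR
    extensions from coverage tracks, spliced-junction tables and long-read
    transcript models; classification of changes between annotation sets;
    reciprocal-best-BLAST-hit protein-length accuracy binning; orthogroup
    copy-pattern classification; and detection of spurious genome-assembly
    duplications from whole-genome alignment coordinates. Ships a synthetic
    genome/annotation/evidence simulator with planted errors so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
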