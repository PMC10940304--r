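Package: zfscan
Title: Genome-Wide C2H2 Zinc-Finger Gene Family Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide characterization of plant
    C2H2 zinc-finger protein (C2H2-ZFP) gene families: detection of C2H2
    fingers from the metal-coordinating C-X(2-4)-C-X12-H(-X(3-5)-H)
    skeleton, typing of each finger by integrity of the plant-specific
    QALGGH motif (Q, M1-M5, D), tandem/dispersed architecture subgrouping
    (1i-4i, t1, t2) with systematic family nomenclature, ProtParam-style
    physicochemical profiling, neighbor-joining phylogeny with bootstrap
    support, Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor
    correction and divergence dating via T = Ks/(2*lambda), promoter
    cis-regulatory element counting from a user-replaceable IUPAC motif
    table, and FPKM expression filtering and differential-expression
    summarization. A synthetic-data generator produces every input with
    known ground truth so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    yaml,
    knitr
Config/testthat/edition: 3
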