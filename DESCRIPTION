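Package: ctrdseq
Title: Co-Translational mRNA Decay Analysis from 5'P Degradome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of 5' monophosphate degradome sequencing (5'Pseq)
    libraries for co-translational mRNA decay (CTRD). Maps aligned read 5'
    ends into transcript coordinates, aggregates metagene profiles anchored
    at stop codons, quantifies three-nucleotide ribosome periodicity,
    computes the per-transcript Terminational Stalling Index (TSI), calls
    CTRD targets across genotypes with fold-change and Wilcoxon statistics,
    tests gene-set overlaps with the hypergeometric distribution, and fits
    first-order mRNA decay to transcription-arrest time courses. Includes a
    seeded synthetic degradome generator with analytic ground truth for
    validating every step of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    graphics,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
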