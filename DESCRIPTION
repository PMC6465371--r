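Package: pcpatools
Title: Detection of Premature Cleavage and Polyadenylation from Nascent
    RNA and Poly(A) 3'-End Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect premature cleavage and polyadenylation (PCPA)
    and its genetic determinants from nascent-RNA (TT-seq) coverage and
    poly(A) 3'-end sequencing. Builds a reduced custom gene annotation from
    transcript abundances, normalizes coverage with spike-in size factors,
    computes metagene and TSS-proximal transcription-dynamics profiles,
    filters internal-priming artifacts from poly(A) peak candidates and
    annotates them hierarchically, and derives per-gene statistics: the
    intron-retention index, PCPA exon- and iQ-scores, intronic
    polyadenylation usage odds ratios, differential expression, gene-set
    permutation z-scores, gene-architecture determinants of PCPA and
    splice-site position-weight-matrix conservation scores. A synthetic-data
    generator produces miniature genomes with planted effects and a ground
    truth table for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
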