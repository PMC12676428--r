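Package: piswarm
Title: Target-Centered Analysis of Pachytene piRNA Swarms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies mRNAs targeted in antisense by swarms of pachytene
    PIWI-interacting RNAs (piRNAs) under a bounded-mismatch rule (at most one
    mismatch across guide nucleotides 2-21), ranks targets by converging
    piRNA weight, traces targeting piRNAs to their genomic source clusters,
    and dissects the pseudogene fragments embedded in those clusters:
    local-alignment discovery, exon composition, 5' truncation, processed
    state and flanking target-site duplications. Also provides
    position-specific nucleotide signatures (1U/10A), ping-pong 5'-overlap
    profiles, metagene profiles over 5'UTR/CDS/3'UTR, and Kolmogorov-Smirnov
    comparison of expression shifts between target groups. A synthetic-data
    generator with full ground truth makes every pipeline stage testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
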