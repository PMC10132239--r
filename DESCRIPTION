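Package: crosslinkr
Title: Integrative Analysis of PAR-CLIP Binding Sites with RNA-seq
    Expression and Alternative Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of PAR-CLIP binding-site clusters for an
    RNA-binding protein together with matched RNA-seq data. Annotates
    clusters against a gene model and summarises their distribution over
    transcript regions, measures replicate concordance of crosslinked
    reads, computes region- and length-matched k-mer enrichment Z-scores,
    profiles binding around 3' splice sites, bins target genes by
    normalized crosslink occupancy (NXPM) and compares knockdown
    fold-change distributions across bins, correlates binding with gene
    architecture, and filters and intersects rMATS-style alternative
    splicing events with the target set. Includes a seeded synthetic-data
    generator (genome, annotation, cluster replicates, expression and
    splicing tables) that emulates the statistical structure these
    analyses assume, so the whole pipeline can be exercised end to end
    without external data.
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
    methods,
    Rcpp,
    stats,
    utils,
    stringi,
    jsonlite,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    rtracklayer
Config/testthat/edition: 3
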