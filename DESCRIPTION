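Package: lnckit
Title: Locus-Scale Characterization of Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational procedures for characterizing a long non-coding RNA
    locus from sequencing and proteomics readouts: in-silico restriction
    digestion and 4C-seq viewpoint profiling (iterative 3'-end trimming and
    mapping, fragment assignment, reads-per-million normalization,
    closest-five-fragment smoothing), splice-junction-based classification and
    relative quantification of nanopore long-read isoforms, Smith-Waterman
    local alignment with gapless conserved-stretch extraction, open reading
    frame enumeration with percentile-windowed coding-potential score
    distributions, RNA-pulldown label-free-quantification enrichment ranking,
    and subcellular fractionation percentages. A seeded synthetic-data module
    generates every input the analyses consume, so the full workflow runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
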