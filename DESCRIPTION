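Package: multikc
Title: Multiple-k/Multiple-C De Novo Transcriptome Assembly, Redundancy
    Depletion, Homology Annotation and Depth-Based Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of the Multiple-k/Multiple-C
    strategy for de novo assembly of short single-end RNA-seq reads from a
    non-model insect and its bacterial endosymbionts. Reads are assembled
    under a grid of de Bruijn hash lengths (k) and coverage cutoffs (C),
    each contig set is depleted of redundancy by greedy identity
    clustering, the per-cell survivors are pooled and depleted again, and
    the merged contigs are annotated by a cascade homology search
    (translated tier first, nucleotide fallback, single top hit per
    contig). Relative transcript abundance is estimated by mapping reads
    back to contigs under a bounded-mismatch rule and summarising
    per-nucleotide depth (reads x read length / contig length). A labelled
    synthetic transcriptome generator (host, polyA-deficient primary
    endosymbiont, rRNA-only secondary endosymbiont) makes the whole
    pipeline testable without any sequencing download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
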