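Package: eceval
Title: Benchmarking Haplotype-Aware Long-Read Error Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates long-read error-correction (EC) tools by comparing
    alignments of raw and corrected reads against a high-quality truth
    assembly. Reference-anchored edit events are extracted from minimap2
    cs tags (or SAM CIGAR/MD), matched per read, and partitioned into
    correct corrections (CC), under-corrections (UC) and over-corrections
    (OC), from which the false discovery rate OC/(CC+OC) and false
    negative rate UC/(CC+UC) are computed. Includes homopolymer
    compression so evaluation can run entirely in HPC space, haplotype /
    chromosome / position classification of reads whose raw and corrected
    alignments disagree, stratification of error rates by BED annotation
    or assembly-derived homopolymer runs, and a fully ground-truthed
    diploid read simulator with a pseudo-corrector so the whole pipeline
    is testable without external aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
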