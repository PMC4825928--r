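Package: spliceff
Title: Intron Retention and Splicing Efficiency Analysis from Spliced Alignments
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-intron retention levels from spliced RNA-seq
    alignments (reads overlapping predicted introns divided by reads aligned
    to the corresponding transcript), classifies introns by retention fold
    change between genotypes with replicate concordance, summarizes affected
    genes, computes suppressor recovery percentages and two-isoform retention
    fractions, and characterizes intron sequence features (splice-site and
    branch-point position frequency matrices, intron lengths, branch-point
    distances). Includes a seeded spliced-read simulator with an analytic
    expected-retention oracle providing ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    GenomeInfoDb,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
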