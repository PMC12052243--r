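Package: svdelnet
Title: Deletion Structural-Variant Calling from Long Reads with a Relational Graph Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects deletion structural variants (>= 50 bp) in microbial
    genomes from long-read alignments. Each read's CIGAR string is turned into
    a small heterogeneous graph (reference-side and read-side nodes; ref-ref,
    ref-read and read-read relations) and classified node-by-node with a
    relational graph convolutional network whose head carries a learnable
    B-spline (Kolmogorov-Arnold) activation layer. Positive deletion nodes are
    consolidated into consensus calls by per-chromosome density clustering and
    a distance/length-ratio fragment-merging rule. Includes a seeded simulator
    that implants deletions into a synthetic reference and emits long reads
    with exact analytic CIGARs, plus VCF output and truth-based evaluation
    over standard deletion length bins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    splines,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
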