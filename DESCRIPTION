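Package: sirnaseed
Title: Detect siRNA Seed-Mediated Off-Target Effects in RNA-Seq Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diagnosing seed-mediated off-target activity of siRNA
    in differential expression experiments. Derives miRNA-style seed site
    patterns (8mer, 7mer-m8, 7mer-A1, 6mer) from a guide strand sequence,
    extracts strand-aware feature sequences (3' UTR, 5' UTR, CDS, exons,
    introns, promoters) from a GTF annotation and genome FASTA, annotates
    differential expression results with per-gene seed match counts, and
    tests for a cumulative fold-change shift in matched genes with a
    one-sided two-sample Kolmogorov-Smirnov comparison of empirical
    cumulative distribution functions. Includes a synthetic fixture
    generator with planted target sites and planted expression shifts for
    validation and power analysis, plotting helpers, and a command line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    ggplot2,
    jsonlite,
    optparse,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
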