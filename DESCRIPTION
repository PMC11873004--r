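Package: fuseseq
Title: Split-Read Gene Fusion Calling with Exon-Boundary and Frame Awareness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene fusions from split-read (chimeric) alignments of
    RNA-seq reads, including anchored multiplex PCR (AMP) libraries. Starting
    from aligned SAM records carrying supplementary-alignment (SA) tags, the
    package consolidates reads by unique molecular identifier and
    soft-clip-adjusted ligation site, transforms CIGAR strings into
    strand-aware query intervals, infers candidate fusion junctions between
    neighboring split alignments, filters them by end-specific mapping-length
    rules, annotates breakpoints with gene, exon, and cDNA position, judges
    exon-boundary status, and infers the reading-frame status of the fused
    transcript. Optional modes rescue alignments in highly repetitive regions
    (pseudogenes) via alternative-alignment coordinates, report whitelisted
    intragenic events such as exon skipping and exon deletion, and suppress
    recurrent artifacts via a blacklist. Reporting includes fusion summaries,
    supporting-read extraction, fusion-junction-defined subclone counts, and a
    two-sided Fisher's exact test for subclone heterogeneity. A seeded
    simulator generates reference sequences, transcript models, and aligned
    split reads with truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Rsamtools,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
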