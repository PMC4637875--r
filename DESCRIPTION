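Package: mirderep
Title: Small RNA Quantification and miRNA Target Derepression Analysis for
    Knockout Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of the computational analyses used in
    miRNA knockout transcriptome studies of CD8+ T cells: small RNA-seq read
    filtering (Illumina QC flag, 3' adapter presence, minimum insert length,
    ambiguous bases) and dominant-isoform miRNA quantification against
    hairpin references; miRNA target derepression analysis via score-binned
    log2 fold-change CDFs compared with two-sided Kolmogorov-Smirnov tests;
    and differential-expression signature enrichment via one-sided Fisher
    exact tests. Ships a seeded synthetic-data generator that emulates the
    small-RNA libraries and paired wild-type/knockout expression tables with
    known ground truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    fgsea,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
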