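Package: guidespec
Title: Off-Target-Aware sgRNA Library Design and Screen Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing CRISPR/CRISPRi/CRISPRa sgRNA libraries that
    target non-coding elements (transcription-factor motifs, transcription
    start sites, candidate cis-regulatory elements) and for diagnosing
    off-target confounding in pooled growth screens. Enumerates candidate
    spacers next to PAM sites, searches genomes for off-target sites within a
    mismatch budget, computes Cutting Frequency Determination (CFD) site
    scores from a weight table and aggregates them into a per-guide
    specificity score in (0,1], applies a guide-filtering stack (GC bounds,
    homopolymers, restriction sites, off-target count thresholds,
    exclusion-region overlap), summarises element targetability, computes
    guide-level log2 fold-change enrichment from screen count matrices, tests
    the specificity-fitness association with an exact 2x2 Fisher quadrant
    analysis, calls elements with concordant depletion evidence before and
    after specificity filtering, rescales ChIP coverage tracks by FRiP
    ratios, and simulates genomes and screens with planted off-target
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
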