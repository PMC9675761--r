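Package: temrkit
Title: Discovery and Mechanistic Characterization of Transposable
    Element-Mediated Rearrangements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis toolkit for transposable element-mediated
    rearrangements (TEMRs): structural variants whose two breakpoints fall
    in distinct transposable element copies of the same class. Provides a
    synthetic-genome generator that plants TE copies and TEMRs of known
    mechanism, ensemble merging of multi-caller structural variant callsets
    by reciprocal overlap with rank-based breakpoint retention, TEMR
    categorization against a RepeatMasker-style annotation, breakpoint
    microhomology reconstruction, homologous-recombination versus
    non-homologous repair mechanism inference by local alignment of
    junction flanks to TE consensus sequences (with Alu monomer retry and
    poly-A/truncation flags), and the downstream enrichment statistics
    (TE density with random-window controls, GC content, copy-number
    estimation from read depth, genic intersection, and exact tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
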