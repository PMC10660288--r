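Package: fgharmonize
Title: Harmonization of Heterogeneous Functional-Genomics Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Config-driven harmonization of heterogeneous functional-genomics
    files - annotated genomic intervals, QTL summary statistics, and chromatin
    interactions - into sorted, bgzip-compressed, tabix-indexed BED-convention
    tracks with standardized per-track and project-level metadata. Handles
    arbitrary delimited-text dialects (delimiters, headers, 0/1-based
    coordinates, chromosome naming), verifies and reorients QTL alleles
    against a variant reference with genome-FASTA fallback, assigns rsIDs,
    annotates target genes, applies per-gene-tissue Benjamini-Hochberg FDR
    correction, splits QTLs by variant type and significance, and expands
    chromatin interactions into per-anchor interact-format records so either
    anchor is region-queryable. Includes a deterministic synthetic-fixture
    generator with recorded ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Rsamtools,
    GenomicRanges,
    IRanges,
    Biostrings,
    S4Vectors,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
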