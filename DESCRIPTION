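Package: sslmap
Title: Substitution Mapping and Allelic Variation Analysis for
    Single-Segment Substitution Line Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with libraries of single segment
    substitution lines (SSSLs): genetic-constitution statistics of an
    introgression-line population (segment totals, means, genome coverage
    and per-chromosome coverage rates), substitution mapping of binary
    traits to physical candidate intervals by intersecting carrier-line
    segments and excluding non-carrier segments, positional allelism
    checks of mapped loci against a catalog of cloned genes, and pairwise
    CDS comparison with variant extraction, indel left-normalization and
    codon-level protein-consequence annotation. A seeded simulator
    generates complete synthetic SSSL data sets (genome, markers,
    marker-delimited segments, planted causal genes, phenotypes and
    mutated CDS pairs) so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
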