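Package: scoredel
Title: Single-Guide CRISPR Deletion Design and Screening for
    LCR-Flanked Copy Number Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design toolkit for engineering recurrent microdeletions
    (such as the 22q11.2 A-B and A-D deletions) with a single CRISPR/Cas9
    guide that targets a homologous sequence shared by the two low copy
    repeats (LCRs) flanking the copy number variant. Enumerates SpCas9
    guide sites, finds protospacers common to both flanking repeats,
    predicts the deletion and inversion products of simultaneous cutting,
    applies a mismatch-count off-target filter with a brute-force search
    that is exact by construction, and cross-verifies designs against
    multiple genome assemblies. Also implements the downstream clone
    screen: delta-delta-Ct relative copy number from qPCR tables,
    deletion calls from in-region versus flanking marker genes, in-silico
    PCR of the screening primer panel, and region-dosage summaries of
    expression or protein-abundance matrices. Ships seeded synthetic-locus,
    Ct-table and expression generators with machine-readable truth tables
    so every computation is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
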