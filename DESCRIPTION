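Package: primerscope
Title: In-Silico Design and Coverage Screening of Degenerate PCR Primers for Mitochondrial rRNA Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the in-silico life cycle of degenerate metabarcoding
    primers targeting the mitochondrial small-subunit (12S) rRNA gene. Parses
    GenBank-format mitochondrial genome records, excises the annotated 12S
    rRNA feature in gene orientation and validates annotations; scans gapped
    multiple alignments for conserved windows and derives IUPAC-degenerate
    consensus primers; performs IUPAC-aware ungapped best-site search of
    primers against sequence collections with mismatch categorisation
    (0 / 1 / 2+), positional mismatch profiling from the 3' end, and amplicon
    length prediction; and emits taxonomy-grouped coverage tables. Includes a
    seeded synthetic-fixture generator that plants primer sites with known
    per-position substitution rates so the whole pipeline is testable without
    any download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
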