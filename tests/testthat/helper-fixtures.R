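# Hand-written GenBank flat-file text, independent of the package's own
# emitter, for parser unit tests.

gb_record_text <- function(accession = "TEST0001",
                           organism = "Testus exemplarius",
                           lineage = "Metazoa; Testophora; Testoclassia",
                           sequence = "ACGTACGTACGTACGTACGT",
                           feature_lines = c(
                             "     rRNA            3..18",
                             "                     /product=\"12S ribosomal RNA\""),
                           declared_bp = NULL) {
  n <- if (is.null(declared_bp)) nchar(sequence) else declared_bp
  seq_lc <- tolower(sequence)
  pos <- seq(1L, nchar(seq_lc), by = 60L)
  seq_lines <- vapply(pos, function(s) {
    chunk <- substr(seq_lc, s, min(nchar(seq_lc), s + 59L))
    p <- seq(1L, nchar(chunk), by = 10L)
    sprintf("%9d %s", s,
            paste(substring(chunk, p, pmin(nchar(chunk), p + 9L)), collapse = " "))
  }, character(1L))
  c(sprintf("LOCUS       %s               %d bp    DNA     circular INV 15-FEB-2011",
            accession, n),
    sprintf("DEFINITION  %s mitochondrion, complete genome.", organism),
    sprintf("ACCESSION   %s", accession),
    sprintf("SOURCE      %s", organism),
    sprintf("  ORGANISM  %s", organism),
    sprintf("            %s.", lineage),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(sequence)),
    feature_lines,
    "ORIGIN",
    seq_lines,
    "//")
}

small_spec <- function(seed = 42L, n = 6L, ...) {
  fixture_spec(seed = seed,
               phyla = c(Alphazoa = n, Betaphora = n),
               ...)
}

excise_all <- function(records, ...) {
  lapply(records, function(r) validate_excised(excise_gene(r, find_ssu_rrna(r)), ...))
}
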