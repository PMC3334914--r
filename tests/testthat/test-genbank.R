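test_that("empty or blank input yields an empty record list", {
  expect_identical(read_genbank(text = character()), list())
  expect_identical(read_genbank(text = c("", "   ")), list())
})

test_that("a hand-written record parses with all fields intact", {
  seq <- paste(rep("ACGTTGCA", 20), collapse = "")  # 160 bp
  txt <- gb_record_text(
    accession = "HW0001", sequence = seq,
    feature_lines = c("     rRNA            complement(11..90)",
                      "                     /product=\"s-rRNA\"",
                      "     tRNA            95..150",
                      "                     /product=\"tRNA-Phe\""))
  recs <- read_genbank(text = txt)
  expect_length(recs, 1)
  r <- recs[[1]]
  expect_identical(r$accession, "HW0001")
  expect_identical(r$organism, "Testus exemplarius")
  expect_identical(r$lineage, c("Metazoa", "Testophora", "Testoclassia"))
  expect_identical(r$sequence, toupper(seq))
  expect_equal(r$length, 160)
  expect_length(r$features, 2)  # source dropped, rRNA + tRNA kept
  rrna <- r$features[[1]]
  expect_identical(rrna$kind, "rRNA")
  expect_identical(rrna$label, "s-rRNA")
  expect_equal(c(rrna$start, rrna$end), c(11, 90))
  expect_identical(rrna$strand, "-")
})

test_that("generator fixtures round-trip through the parser to their truth", {
  spec <- small_spec(seed = 5, n = 8, strand_minus_prob = 0.5)
  d <- generate_dataset(spec)
  recs <- read_genbank(text = d$genbank)
  expect_length(recs, nrow(d$truth))
  for (i in seq_along(recs)) {
    expect_identical(recs[[i]]$accession, d$truth$accession[i])
    expect_identical(recs[[i]]$lineage[2], d$truth$phylum[i])
    f <- find_ssu_rrna(recs[[i]])
    expect_identical(f$strand, d$truth$strand[i])
    expect_equal(f$start, d$truth$gene_start[i])
    expect_equal(f$end, d$truth$gene_end[i])
  }
  # at least one record on each strand under this seed
  expect_setequal(unique(d$truth$strand), c("+", "-"))
})

test_that("malformed records raise errors naming the LOCUS", {
  txt <- gb_record_text(accession = "BAD01", sequence = "ACGTACGTAC",
                        feature_lines = c("     rRNA            3..99",
                                          "                     /product=\"12S ribosomal RNA\""))
  expect_error(read_genbank(text = txt), "BAD01.*exceeds sequence length")
  txt2 <- gb_record_text(accession = "BAD02", sequence = "ACGTACGTAC",
                         declared_bp = 99)
  expect_error(read_genbank(text = txt2), "BAD02.*declares 99")
})

test_that("find_ssu_rrna honours dialects, ambiguity and compound locations", {
  mk <- function(feature_lines) {
    read_genbank(text = gb_record_text(sequence = strrep("ACGT", 30),
                                       feature_lines = feature_lines))[[1]]
  }
  r <- mk(c("     rRNA            3..100",
            "                     /product=\"12S ribosomal RNA\""))
  expect_identical(find_ssu_rrna(r)$label, "12S ribosomal RNA")
  r16 <- mk(c("     rRNA            3..100",
              "                     /product=\"16S ribosomal RNA\""))
  expect_null(find_ssu_rrna(r16))
  # a non-rRNA feature never matches, whatever its label
  rgene <- mk(c("     gene            3..100",
                "                     /gene=\"12S\""))
  expect_null(find_ssu_rrna(rgene))
  rdup <- mk(c("     rRNA            3..50",
               "                     /product=\"s-rRNA\"",
               "     rRNA            60..110",
               "                     /product=\"s-rRNA\""))
  expect_error(find_ssu_rrna(rdup), "ambiguous annotation")
  rjoin <- mk(c("     rRNA            join(3..50,60..100)",
                "                     /product=\"12S ribosomal RNA\""))
  expect_error(find_ssu_rrna(rjoin), "ambiguous annotation")
})

test_that("excise_gene returns the gene 5'->3' on either strand", {
  seq <- "AACCGGTTAACC"
  r <- read_genbank(text = gb_record_text(
    sequence = seq,
    feature_lines = c("     rRNA            1..12",
                      "                     /product=\"rrnS\"")))[[1]]
  expect_identical(excise_gene(r, r$features[[1]])$sequence, seq)  # identity
  rm <- read_genbank(text = gb_record_text(
    sequence = seq,
    feature_lines = c("     rRNA            complement(1..4)",
                      "                     /product=\"rrnS\"")))[[1]]
  expect_identical(excise_gene(rm, rm$features[[1]])$sequence, "GGTT")
  g <- excise_gene(r, r$features[[1]])
  expect_equal(g$length, nchar(seq))
  expect_identical(g$lineage, r$lineage)
})

test_that("validate_excised applies length and ambiguity bounds with reasons", {
  mk_gene <- function(seq) {
    structure(list(accession = "X", organism = "x", lineage = "Metazoa",
                   sequence = seq, start = 1L, end = nchar(seq), strand = "+",
                   length = nchar(seq), status = "kept", reason = ""),
              class = "excised_gene")
  }
  short <- validate_excised(mk_gene(strrep("A", 50)))
  expect_identical(short$status, "removed")
  expect_identical(short$reason, "too short")
  ok <- validate_excised(mk_gene(strrep("ACGT", 200)))
  expect_identical(ok$status, "kept")
  long <- validate_excised(mk_gene(strrep("ACGT", 700)))
  expect_identical(long$reason, "too long")
  ambig <- validate_excised(mk_gene(paste0(strrep("N", 100), strrep("ACGT", 100))))
  expect_identical(ambig$reason, "too many ambiguous bases")
  # monotonicity: widening the bounds never flips kept -> removed
  set.seed(9)
  for (i in 1:40) {
    g <- mk_gene(random_acgt(sample(50:3000, 1)))
    narrow <- validate_excised(g, 400, 1500)
    wide <- validate_excised(g, 300, 2500)
    if (narrow$status == "kept") expect_identical(wide$status, "kept")
  }
})

test_that("excised genes round-trip through FASTA and manifest", {
  spec <- small_spec(seed = 12, n = 5)
  d <- generate_dataset(spec)
  genes <- excise_all(read_genbank(text = d$genbank))
  fa <- tempfile(fileext = ".fasta"); man <- tempfile(fileext = ".tsv")
  write_excised(genes, fasta = fa, manifest = man)
  back <- Biostrings::readDNAStringSet(fa)
  kept <- Filter(function(g) g$status == "kept", genes)
  expect_equal(length(back), length(kept))
  expect_identical(unname(as.character(back)),
                   vapply(kept, `[[`, "", "sequence"))
  m <- read.delim(man)
  expect_identical(m$accession, d$truth$accession)
  expect_true(all(m$status == "kept"))
})
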