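test_that("column_profiles tallies bases, gaps and majority correctly", {
  aln <- alignment_matrix(c("AAA", "AAA", "AAA"))
  p <- column_profiles(aln)
  expect_equal(p$majority_freq, rep(1, 3))
  expect_equal(p$gap_fraction, rep(0, 3))
  expect_identical(p$majority_base, rep("A", 3))

  aln2 <- alignment_matrix(c("A", "A", "G", "-"))
  p2 <- column_profiles(aln2)
  expect_identical(p2$majority_base, "A")
  expect_equal(p2$majority_freq, 2 / 3)
  expect_equal(p2$gap_fraction, 1 / 4)

  # ties break alphabetically; N excluded from the denominator
  p3 <- column_profiles(alignment_matrix(c("T", "A", "N", "-")))
  expect_identical(p3$majority_base, "A")
  expect_equal(p3$majority_freq, 1 / 2)
})

test_that("column_profiles equals an independent per-column tally", {
  set.seed(33)
  rows <- replicate(9, paste(sample(c("A", "C", "G", "T", "N", "-"), 40,
                                    replace = TRUE), collapse = ""))
  p <- column_profiles(alignment_matrix(rows))
  chars <- do.call(rbind, strsplit(rows, ""))
  for (j in seq_len(40)) {
    col <- chars[, j]
    for (b in c("A", "C", "G", "T")) expect_equal(p[[b]][j], sum(col == b))
    expect_equal(p$gap[j], sum(col == "-"))
    expect_equal(p$other[j], sum(!col %in% c("A", "C", "G", "T", "-")))
    denom <- sum(col %in% c("A", "C", "G", "T"))
    if (denom > 0) {
      cnt <- table(factor(col, levels = c("A", "C", "G", "T")))
      expect_equal(p$majority_freq[j], max(cnt) / denom)
    }
  }
})

test_that("find_conserved_regions reports maximal qualifying runs", {
  ident <- alignment_matrix(rep(strrep("ACGT", 10), 4))
  r <- find_conserved_regions(column_profiles(ident), min_length = 20)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(1, 40))
  expect_equal(r$mean_majority_freq, 1)

  expect_equal(nrow(find_conserved_regions(column_profiles(ident),
                                           min_length = 41)), 0)
})

test_that("planted conserved blocks are recovered exactly, with and without gaps", {
  for (seed in c(2, 17)) {
    spec <- fixture_spec(seed = seed, phyla = c(A = 24L), n_align = 48)
    for (gapped in c(FALSE, TRUE)) {
      a <- generate_alignment(spec, gapped = gapped)
      reg <- find_conserved_regions(column_profiles(a$alignment))
      expect_equal(nrow(reg), 2)
      expect_equal(c(reg$start[1], reg$end[1]), a$truth$fwd_cols)
      expect_equal(c(reg$start[2], reg$end[2]), a$truth$rev_cols)
    }
  }
})

test_that("reported regions are maximal and internally qualifying", {
  spec <- fixture_spec(seed = 8, phyla = c(A = 24L))
  a <- generate_alignment(spec)
  prof <- column_profiles(a$alignment)
  reg <- find_conserved_regions(prof, min_length = 20,
                                min_majority_freq = 0.75, max_gap_fraction = 0.10)
  qualifies <- function(j) {
    !is.na(prof$majority_freq[j]) && prof$majority_freq[j] >= 0.75 &&
      prof$gap_fraction[j] <= 0.10
  }
  for (i in seq_len(nrow(reg))) {
    expect_true(all(vapply(reg$start[i]:reg$end[i], qualifies, logical(1))))
    if (reg$start[i] > 1) expect_false(qualifies(reg$start[i] - 1))
    if (reg$end[i] < nrow(prof)) expect_false(qualifies(reg$end[i] + 1))
  }
})

test_that("degenerate_consensus covers included bases and the majority", {
  mono <- alignment_matrix(rep(strrep("A", 25), 4))
  p <- degenerate_consensus(mono, list(start = 1, end = 25), orientation = "forward")
  expect_identical(p$sequence, strrep("A", 25))
  expect_equal(p$degeneracy, 1)

  # 60% A / 40% G column -> R at include_freq 0.1
  rows <- c(rep("A", 6), rep("G", 4))
  mix <- alignment_matrix(rows)
  pm <- degenerate_consensus(mix, list(start = 1, end = 1), include_freq = 0.1)
  expect_identical(pm$sequence, "R")

  # reverse orientation emits the reverse complement of the sense consensus
  aln <- alignment_matrix(rep("AACCG", 4))
  pr <- degenerate_consensus(aln, list(start = 1, end = 5), orientation = "reverse")
  expect_identical(pr$sequence, "CGGTT")

  gappy <- alignment_matrix(c("-A", "-A", "-A"))
  expect_error(degenerate_consensus(gappy, list(start = 1, end = 2)),
               "no unambiguous residues")
})

test_that("planted degenerate site strings are reconstructed from the alignment", {
  spec <- fixture_spec(seed = 21, phyla = c(A = 24L))
  a <- generate_alignment(spec)
  fwd <- degenerate_consensus(a$alignment,
                              list(start = a$truth$fwd_cols[1], end = a$truth$fwd_cols[2]),
                              orientation = "forward")
  rev <- degenerate_consensus(a$alignment,
                              list(start = a$truth$rev_cols[1], end = a$truth$rev_cols[2]),
                              orientation = "reverse")
  expect_identical(fwd$sequence, a$truth$fwd_primer)
  expect_identical(rev$sequence, a$truth$rev_primer)
})

test_that("lowering include_freq never decreases degeneracy", {
  set.seed(55)
  rows <- replicate(20, random_acgt(30))
  aln <- alignment_matrix(rows)
  region <- list(start = 1, end = 30)
  degs <- vapply(c(0.5, 0.3, 0.2, 0.1, 0.05),
                 function(f) degenerate_consensus(aln, region, f)$degeneracy,
                 numeric(1))
  expect_true(all(diff(degs) >= 0))
})

test_that("rows made of included residues match the consensus with zero mismatches", {
  spec <- fixture_spec(seed = 4, phyla = c(A = 24L))
  a <- generate_alignment(spec)
  fwd <- degenerate_consensus(a$alignment,
                              list(start = a$truth$fwd_cols[1], end = a$truth$fwd_cols[2]),
                              orientation = "forward")
  pc <- strsplit(fwd$sequence, "")[[1]]
  for (row in a$alignment$rows[1:10]) {
    site <- strsplit(substr(row, a$truth$fwd_cols[1], a$truth$fwd_cols[2]), "")[[1]]
    expect_true(all(iupac_match(site, pc)))
  }
})
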