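# Seeded, truth-annotated synthetic fixtures: mitogenome-like GenBank
# records with a planted SSU-rRNA-analog gene carrying two primer sites
# around a variable insert, plus a block-structured "alignment" for
# conservation tests. Every stochastic choice derives from the spec seed, so
# identical specs give byte-identical fixtures.

BASES <- c("A", "C", "G", "T")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Specification of a synthetic screening cohort
#'
#' Describes a seeded cohort of annotated mitogenome-like records in which a
#' gene of the form `[left flank][forward site][insert][revcomp reverse
#' site][right flank]` is planted, with per-position substitution
#' probabilities inside each primer site (indexed from the primer's 3' end;
#' an intended mismatch is always drawn from outside the code's expansion
#' set, so the truth mismatch count is exact). The defaults emulate the
#' statistical structure of a published-style metazoan screen: four "phyla"
#' of 500 genomes each, insert lengths spanning 329-1046 bp with 56/64 of
#' the mass in the 400-600 bp band, a low baseline substitution rate, and
#' one divergent phylum with strong 3'-end mismatch hotspots.
#'
#' @param seed integer seed; same seed + spec gives identical fixtures.
#' @param phyla named integer vector: records per phylum label.
#' @param fwd_site,rev_site planted primer site sequences (IUPAC, 5'-3';
#'   both synthetic, not published oligos).
#' @param site_sub_probs `NULL` for the defaults, or a list with entries
#'   `fwd` and `rev` (numeric per-position vectors, position 1 = 3' end)
#'   applied to all phyla, or a named per-phylum list of such lists.
#' @param flank_len,background_len `c(min, max)` uniform ranges (bp) for
#'   the within-gene flanks and the extragenic background on each side.
#' @param insert_range,insert_band,insert_band_prob insert lengths are drawn
#'   uniformly from `insert_band` with probability `insert_band_prob`, else
#'   uniformly from `insert_range`.
#' @param strand_minus_prob probability a record carries the gene on the
#'   minus strand.
#' @param corrupt_frac fraction of records whose annotation is deliberately
#'   corrupted (modes cycled among shifted / truncated / mislabelled).
#' @param n_align,align_insert_len rows and fixed insert width of the
#'   companion conservation alignment.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         phyla = c(Alphazoa = 500L, Betaphora = 500L,
                                   Gammorpha = 500L, Deltonema = 500L),
                         fwd_site = "CGYAAWGGTCCAGCTTRAGCTA",
                         rev_site = "TGGTRCTKAGCACGTTCAMGTT",
                         site_sub_probs = NULL,
                         flank_len = c(40L, 80L),
                         background_len = c(150L, 350L),
                         insert_range = c(329L, 1046L),
                         insert_band = c(400L, 600L),
                         insert_band_prob = 56 / 64,
                         strand_minus_prob = 0.3,
                         corrupt_frac = 0,
                         n_align = 64L,
                         align_insert_len = 120L) {
  Lf <- nchar(fwd_site); Lr <- nchar(rev_site)
  iupac_bits(fwd_site, "fwd_site"); iupac_bits(rev_site, "rev_site")
  if (is.null(site_sub_probs)) {
    base_f <- rep(0.02, Lf); base_r <- rep(0.02, Lr)
    hot_f <- base_f; hot_f[c(3L, 7L, 12L, 17L)] <- 0.70
    hot_r <- base_r; hot_r[c(8L, 9L, 12L, 19L)] <- 0.70
    nm <- names(phyla)
    site_sub_probs <- stats::setNames(
      c(rep(list(list(fwd = base_f, rev = base_r)), max(0L, length(nm) - 1L)),
        list(list(fwd = hot_f, rev = hot_r))),
      nm)
  } else if (!is.null(site_sub_probs$fwd)) {
    site_sub_probs <- stats::setNames(
      rep(list(site_sub_probs), length(phyla)), names(phyla))
  }
  for (p in site_sub_probs) {
    stopifnot(length(p$fwd) == Lf, length(p$rev) == Lr,
              all(p$fwd >= 0 & p$fwd <= 1), all(p$rev >= 0 & p$rev <= 1))
  }
  stopifnot(!is.null(names(phyla)), all(phyla >= 0),
            corrupt_frac >= 0, corrupt_frac <= 1,
            strand_minus_prob >= 0, strand_minus_prob <= 1)
  structure(
    list(seed = as.integer(seed), phyla = phyla,
         fwd_site = toupper(fwd_site), rev_site = toupper(rev_site),
         site_sub_probs = site_sub_probs,
         flank_len = flank_len, background_len = background_len,
         insert_range = insert_range, insert_band = insert_band,
         insert_band_prob = insert_band_prob,
         strand_minus_prob = strand_minus_prob,
         corrupt_frac = corrupt_frac,
         n_align = as.integer(n_align),
         align_insert_len = as.integer(align_insert_len)),
    class = "fixture_spec"
  )
}

# Realize one primer site: concrete bases drawn from each code's expansion,
# then per-position substitutions forced outside the expansion. sub_probs is
# indexed from the 3' end. Returns the sequence and the number of planted
# mismatches.
realize_site <- function(site, sub_probs) {
  codes <- strsplit(site, "", fixed = TRUE)[[1L]]
  L <- length(codes)
  bases <- vapply(codes, function(cc) {
    ex <- iupac_expand(cc)
    ex[sample.int(length(ex), 1L)]
  }, character(1L))
  p53 <- rev(sub_probs)  # to 5'->3' indexing
  mm <- 0L
  for (i in seq_len(L)) {
    ex <- iupac_expand(codes[i])
    if (length(ex) >= 4L) next  # N-like code: every base matches
    if (stats::runif(1L) < p53[i]) {
      out <- setdiff(BASES, ex)
      bases[i] <- out[sample.int(length(out), 1L)]
      mm <- mm + 1L
    }
  }
  list(sequence = paste(bases, collapse = ""), mismatches = mm)
}

draw_insert_len <- function(spec) {
  if (stats::runif(1L) < spec$insert_band_prob)
    sample(spec$insert_band[1L]:spec$insert_band[2L], 1L)
  else
    sample(spec$insert_range[1L]:spec$insert_range[2L], 1L)
}

FIXTURE_DIALECTS <- c("12S ribosomal RNA", "s-rRNA", "small subunit ribosomal RNA",
                      "rrnS")

#' Generate a seeded synthetic screening dataset with its truth table
#'
#' Produces GenBank-format fixture text (one record per synthetic genome,
#' with an rRNA feature under a rotating annotation dialect and a three-level
#' fake lineage `Metazoa; <phylum>; <class>`), a companion conservation
#' alignment (see [generate_alignment()]), and a truth table recording the
#' planted gene coordinates, strand, per-primer mismatch counts and
#' categories, insert length and corruption status of every record.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, writes `fixture.gb`,
#'   `alignment.fasta` and `truth.tsv` there.
#' @return list with `genbank` (character vector of flat-file lines),
#'   `alignment` (an `alignment_matrix`), `alignment_truth` (planted block
#'   coordinates and intended primer strings) and `truth` (data frame).
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  out <- with_seed(spec$seed, {
    n_total <- sum(spec$phyla)
    phylum_of <- rep(names(spec$phyla), spec$phyla)
    corrupt <- rep(FALSE, n_total)
    if (spec$corrupt_frac > 0) {
      n_bad <- round(spec$corrupt_frac * n_total)
      corrupt[sample.int(n_total, n_bad)] <- TRUE
    }
    modes <- c("shifted", "truncated", "mislabelled")
    rows <- vector("list", n_total)
    gb <- vector("list", n_total)
    fwd_bits <- iupac_bits(spec$fwd_site)
    rev_bits <- iupac_bits(reverse_complement(spec$rev_site))
    for (i in seq_len(n_total)) {
      ph <- phylum_of[i]
      probs <- spec$site_sub_probs[[ph]]
      # rejection-sample until the planted sites are the unique best binding
      # sites in the gene, so the truth offsets and counts hold by
      # construction (a random flank or insert can otherwise tie them)
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 1000L)
          stop("could not plant a unique best binding site; site sequences may be too repetitive or too degenerate", call. = FALSE)
        fwd <- realize_site(spec$fwd_site, probs$fwd)
        rev_ <- realize_site(spec$rev_site, probs$rev)
        lf <- random_dna(sample(spec$flank_len[1L]:spec$flank_len[2L], 1L))
        rf <- random_dna(sample(spec$flank_len[1L]:spec$flank_len[2L], 1L))
        ins_len <- draw_insert_len(spec)
        insert <- random_dna(ins_len)
        gene <- paste0(lf, fwd$sequence, insert,
                       reverse_complement(rev_$sequence), rf)
        gbits <- iupac_bits(gene)
        fb <- .scan_best_site(fwd_bits, gbits)
        rb <- .scan_best_site(rev_bits, gbits)
        if (fb[1L] == nchar(lf) && fb[2L] == fwd$mismatches &&
            rb[1L] == nchar(lf) + nchar(fwd$sequence) + ins_len &&
            rb[2L] == rev_$mismatches) break
      }
      up <- random_dna(sample(spec$background_len[1L]:spec$background_len[2L], 1L))
      down <- random_dna(sample(spec$background_len[1L]:spec$background_len[2L], 1L))
      minus <- stats::runif(1L) < spec$strand_minus_prob
      genome <- paste0(up, if (minus) reverse_complement(gene) else gene, down)
      gstart <- nchar(up) + 1L
      gend <- nchar(up) + nchar(gene)
      label <- FIXTURE_DIALECTS[1L + (i - 1L) %% length(FIXTURE_DIALECTS)]
      mode <- NA_character_
      fstart <- gstart; fend <- gend
      if (corrupt[i]) {
        mode <- modes[1L + (i - 1L) %% length(modes)]
        if (mode == "shifted") {
          fstart <- fend - 60L   # 5' coordinate slipped: 61 bp remnant
        } else if (mode == "truncated") {
          fend <- fstart + 39L   # 40 bp stub
        } else {
          label <- "16S ribosomal RNA"
        }
      }
      acc <- sprintf("SYN%05d", i)
      organism <- sprintf("%s specimen%d", sub("a$", "us", ph), i)
      lineage <- c("Metazoa", ph, paste0(ph, "classia"))
      gb[[i]] <- emit_genbank(acc, organism, lineage, genome,
                              fstart, fend, if (minus) "-" else "+", label)
      rows[[i]] <- data.frame(
        accession = acc, organism = organism, phylum = ph,
        strand = if (minus) "-" else "+",
        gene_start = gstart, gene_end = gend, gene_length = nchar(gene),
        insert_length = ins_len,
        fwd_mismatch = if (corrupt[i]) NA_integer_ else fwd$mismatches,
        rev_mismatch = if (corrupt[i]) NA_integer_ else rev_$mismatches,
        fwd_category = if (corrupt[i]) NA_character_ else
          as.character(categorize(fwd$mismatches)),
        rev_category = if (corrupt[i]) NA_character_ else
          as.character(categorize(rev_$mismatches)),
        corrupted = corrupt[i], corrupt_mode = mode,
        stringsAsFactors = FALSE
      )
    }
    # the companion alignment is only realisable when every site code has
    # degeneracy <= 3 (see generate_alignment); otherwise it is omitted
    aln <- tryCatch(generate_alignment(spec), error = function(e) NULL)
    list(genbank = unlist(gb), truth = do.call(rbind, rows),
         alignment = aln$alignment, alignment_truth = aln$truth)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(out$genbank, file.path(dir, "fixture.gb"))
    if (!is.null(out$alignment)) {
      seqs <- Biostrings::BStringSet(out$alignment$rows)
      names(seqs) <- out$alignment$ids
      Biostrings::writeXStringSet(seqs, file.path(dir, "alignment.fasta"))
    }
    utils::write.table(out$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate a block-structured conservation alignment with known truth
#'
#' Rows have the form `[forward block][insert][reverse block]`. Block
#' columns realise the intended IUPAC code by exact count allocation: the
#' majority base gets ~78% of rows and every other base of the code's
#' expansion ~11%, so under thresholds of 0.75 majority frequency and 0.10
#' inclusion frequency the conserved-region finder recovers exactly the
#' planted intervals and the degenerate consensus reconstructs the intended
#' code string. Insert columns are shuffled balanced assignments of the four
#' bases (majority frequency at most `ceiling(n/4)/n`), so non-conservation
#' of the insert holds by construction. Codes with all four bases (N) cannot
#' satisfy both thresholds simultaneously and are rejected.
#'
#' @param spec a [fixture_spec()]; uses `n_align`, `align_insert_len`,
#'   `fwd_site`, `rev_site` and `seed`.
#' @param gapped plant gap runs in the insert of ~30% of rows, to exercise
#'   gap-fraction handling.
#' @return list with `alignment` (an `alignment_matrix`) and `truth`
#'   (`fwd_cols`, `rev_cols` as `c(start, end)`, and the intended
#'   `fwd_primer` / `rev_primer` IUPAC strings).
#' @export
generate_alignment <- function(spec, gapped = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_align
  if (n < 24L)
    stop("n_align must be at least 24 so block columns can realise both the 0.75 majority and 0.10 inclusion thresholds", call. = FALSE)
  with_seed(spec$seed + 1L, {
    fwd_codes <- strsplit(spec$fwd_site, "", fixed = TRUE)[[1L]]
    rev_sense <- reverse_complement(spec$rev_site)
    rev_codes <- strsplit(rev_sense, "", fixed = TRUE)[[1L]]
    block_col <- function(code) {
      ex <- iupac_expand(code)
      s <- length(ex)
      if (s > 3L)
        stop("planted block codes must have degeneracy <= 3", call. = FALSE)
      minor <- if (s == 1L) integer() else rep(ceiling(0.105 * n), s - 1L)
      m <- n - sum(minor)
      if (m / n < 0.75)
        stop("n_align too small to realise this degenerate code", call. = FALSE)
      sample(c(rep(ex[1L], m), rep(ex[-1L], times = minor)))
    }
    insert_col <- function() sample(rep(BASES, length.out = n))
    Li <- spec$align_insert_len
    cols <- c(lapply(fwd_codes, block_col),
              replicate(Li, insert_col(), simplify = FALSE),
              lapply(rev_codes, block_col))
    m <- do.call(cbind, cols)
    if (gapped) {
      gap_rows <- sample.int(n, max(1L, round(0.3 * n)))
      for (r in gap_rows) {
        glen <- sample(5L:20L, 1L)
        gstart <- length(fwd_codes) + sample.int(Li - glen, 1L)
        m[r, gstart:(gstart + glen - 1L)] <- "-"
      }
    }
    rows <- apply(m, 1L, paste, collapse = "")
    aln <- alignment_matrix(rows, sprintf("row%03d", seq_len(n)))
    Lf <- length(fwd_codes); Lr <- length(rev_codes)
    list(alignment = aln,
         truth = list(
           fwd_cols = c(1L, Lf),
           rev_cols = c(Lf + Li + 1L, Lf + Li + Lr),
           fwd_primer = spec$fwd_site,
           rev_primer = spec$rev_site))
  })
}

#' Corrupt the SSU rRNA annotation of a parsed genome record
#'
#' Emulates the mis-annotated genomes a real screen has to discard:
#' `shifted` slips the feature's 5' coordinate downstream leaving a short
#' remnant window, `truncated` cuts the feature to a 40 bp stub, and
#' `mislabelled` renames it to a 16S product so no SSU dialect matches.
#'
#' @param record a `genome_record` with at least one rRNA feature.
#' @param mode one of `"shifted"`, `"truncated"`, `"mislabelled"`.
#' @return the modified record.
#' @export
corrupt_annotation <- function(record, mode = c("shifted", "truncated", "mislabelled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "genome_record"))
  idx <- which(vapply(record$features, function(f) identical(f$kind, "rRNA"),
                      logical(1L)))
  if (length(idx) == 0L) stop("record has no rRNA feature", call. = FALSE)
  i <- idx[1L]
  f <- record$features[[i]]
  if (mode == "shifted") {
    f$start <- max(1L, f$end - 60L)
  } else if (mode == "truncated") {
    f$end <- min(record$length, f$start + 39L)
  } else {
    f$label <- "16S ribosomal RNA"
  }
  record$features[[i]] <- f
  record
}

# Emit one GenBank flat-file record as a character vector of lines.
emit_genbank <- function(accession, organism, lineage, sequence,
                         fstart, fend, strand, label) {
  n <- nchar(sequence)
  loc <- if (strand == "-") sprintf("complement(%d..%d)", fstart, fend)
         else sprintf("%d..%d", fstart, fend)
  seq_lc <- tolower(sequence)
  starts <- seq(1L, n, by = 60L)
  seq_lines <- vapply(starts, function(s) {
    chunk <- substr(seq_lc, s, min(n, s + 59L))
    pos <- seq(1L, nchar(chunk), by = 10L)
    tens <- substring(chunk, pos, pmin(nchar(chunk), pos + 9L))
    sprintf("%9d %s", s, paste(tens, collapse = " "))
  }, character(1L))
  c(
    sprintf("LOCUS       %s            %d bp    DNA     circular INV 01-JAN-2026",
            accession, n),
    sprintf("DEFINITION  %s mitochondrion, complete genome (synthetic fixture).",
            organism),
    sprintf("ACCESSION   %s", accession),
    sprintf("SOURCE      %s", organism),
    sprintf("  ORGANISM  %s", organism),
    sprintf("            %s.", paste(lineage, collapse = "; ")),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    sprintf("                     /organism=\"%s\"", organism),
    sprintf("     rRNA            %s", loc),
    sprintf("                     /product=\"%s\"", label),
    "ORIGIN",
    seq_lines,
    "//"
  )
}
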