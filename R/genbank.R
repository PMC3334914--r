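# GenBank flat-file parsing and 12S rRNA gene excision.
#
# Coordinates: GenBank is 1-based inclusive at the file boundary; internally
# features keep those numbers (start/end, 1-based inclusive) and all
# subsetting uses substr() on the normalised uppercase sequence, so no
# half-open arithmetic leaks into user-visible objects.

#' Default annotation dialects for the mitochondrial small-subunit rRNA
#'
#' Label patterns (matched case-insensitively as substrings) under which
#' mitogenome annotators commonly file the 12S / small-subunit rRNA gene.
#' @export
ssu_dialects <- function() {
  c("12S", "s-rRNA", "rrnS", "small subunit ribosomal RNA",
    "12S ribosomal RNA", "MT-RNR1")
}

new_genome_record <- function(accession, organism, lineage, sequence, features) {
  structure(
    list(accession = accession, organism = organism, lineage = lineage,
         sequence = sequence, features = features,
         length = nchar(sequence)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s  %s  (%d bp, %d features)\n  lineage: %s\n",
              x$accession, x$organism, x$length, length(x$features),
              paste(x$lineage, collapse = "; ")))
  invisible(x)
}

#' Parse GenBank flat-file text into genome records
#'
#' Minimal offline parser for multi-record GenBank flat files (plain or
#' gzip): LOCUS, ACCESSION, ORGANISM (name plus the indented lineage lines),
#' the FEATURES table (all feature classes retained, with
#' `complement(a..b)` strand handling; `join`/`order` compound locations are
#' kept but flagged), and the ORIGIN sequence. Feature coordinates beyond the
#' sequence length, or records without sequence, raise an error naming the
#' offending LOCUS.
#'
#' @param path path to a GenBank flat file (`.gb`/`.gbk`, optionally `.gz`),
#'   or a character vector of lines via `text`.
#' @param text optional character vector of GenBank lines (overrides `path`).
#' @return list of `genome_record` objects, one per LOCUS; empty input gives
#'   an empty list. Each feature is a list with `kind`, `label`, `start`,
#'   `end` (1-based inclusive), `strand` (`"+"`/`"-"`) and `compound`.
#' @export
read_genbank <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(is.character(path), length(path) == 1L)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    text <- readLines(con, warn = FALSE)
  }
  if (length(text) == 0L) return(list())
  locus_at <- grep("^LOCUS", text)
  if (length(locus_at) == 0L) {
    if (all(!nzchar(trimws(text)))) return(list())
    stop("no LOCUS line found in GenBank input", call. = FALSE)
  }
  end_at <- c(locus_at[-1L] - 1L, length(text))
  lapply(seq_along(locus_at), function(i) {
    parse_one_genbank(text[locus_at[i]:end_at[i]])
  })
}

parse_one_genbank <- function(lines) {
  locus_name <- sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[1L])
  fail <- function(msg) {
    stop(sprintf("malformed GenBank record '%s': %s", locus_name, msg),
         call. = FALSE)
  }

  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line)) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1L])), "\\s+")[[1L]][1L]
  } else locus_name
  if (is.na(accession) || !nzchar(accession)) accession <- locus_name

  org_at <- grep("^\\s{2}ORGANISM", lines)
  organism <- ""
  lineage <- character()
  if (length(org_at)) {
    organism <- trimws(sub("^\\s{2}ORGANISM", "", lines[org_at[1L]]))
    j <- org_at[1L] + 1L
    lin_lines <- character()
    while (j <= length(lines) && grepl("^\\s{10,}\\S", lines[j])) {
      lin_lines <- c(lin_lines, trimws(lines[j]))
      j <- j + 1L
    }
    lin <- paste(lin_lines, collapse = " ")
    lin <- sub("\\.$", "", lin)
    lineage <- trimws(strsplit(lin, ";", fixed = TRUE)[[1L]])
    lineage <- lineage[nzchar(lineage)]
  }

  feat_at <- grep("^FEATURES", lines)
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L) fail("no ORIGIN sequence block")
  origin_at <- origin_at[1L]

  # sequence: strip coordinates, blanks and the terminator
  seq_lines <- lines[(origin_at + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) fail("empty sequence")

  declared <- suppressWarnings(
    as.integer(sub("^LOCUS\\s+\\S+\\s+(\\d+)\\s+bp.*$", "\\1", lines[1L]))
  )
  if (!is.na(declared) && declared != nchar(sequence))
    fail(sprintf("LOCUS declares %d bp but ORIGIN has %d", declared, nchar(sequence)))

  features <- list()
  if (length(feat_at)) {
    fl <- lines[(feat_at[1L] + 1L):(origin_at - 1L)]
    key_at <- grep("^\\s{5}\\S", fl)
    for (k in seq_along(key_at)) {
      block <- fl[key_at[k]:(if (k < length(key_at)) key_at[k + 1L] - 1L else length(fl))]
      kind <- sub("^\\s{5}(\\S+).*$", "\\1", block[1L])
      if (kind == "source") next
      # location may wrap onto continuation lines before the first qualifier
      qual_start <- grep("^\\s+/", block)
      loc_end <- if (length(qual_start)) qual_start[1L] - 1L else length(block)
      loc <- paste(trimws(sub("^\\s{5}\\S+", "", block[seq_len(loc_end)])), collapse = "")
      parsed <- parse_location(loc)
      if (is.null(parsed)) fail(sprintf("unparseable feature location '%s'", loc))
      if (parsed$end > nchar(sequence))
        fail(sprintf("feature %s end %d exceeds sequence length %d",
                     kind, parsed$end, nchar(sequence)))
      if (parsed$start < 1L) fail("feature start below 1")
      label <- if (length(qual_start)) {
        feature_label(paste(trimws(block[qual_start[1L]:length(block)]), collapse = " "))
      } else ""
      features[[length(features) + 1L]] <- list(
        kind = kind, label = label,
        start = parsed$start, end = parsed$end,
        strand = parsed$strand, compound = parsed$compound
      )
    }
  }
  new_genome_record(accession, organism, lineage, sequence, features)
}

parse_location <- function(loc) {
  loc <- gsub("[<>]", "", loc)
  strand <- "+"
  compound <- grepl("join|order", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  nums <- suppressWarnings(as.integer(regmatches(loc, gregexpr("\\d+", loc))[[1L]]))
  if (length(nums) < 1L || anyNA(nums)) return(NULL)
  list(start = min(nums), end = max(nums), strand = strand, compound = compound)
}

feature_label <- function(qual_text) {
  for (q in c("product", "gene", "note")) {
    m <- regmatches(qual_text,
                    regexec(sprintf('/%s="([^"]*)"', q), qual_text))[[1L]]
    if (length(m) == 2L && nzchar(m[2L])) return(m[2L])
  }
  ""
}

#' Locate the small-subunit (12S) rRNA feature of a genome record
#'
#' Scans the record's rRNA features for a label matching any annotation
#' dialect (case-insensitive substring match). Exactly one match is
#' returned; none gives `NULL`; two or more distinct matches — or a single
#' match with a compound (`join`/`order`) location — signal an annotation
#' that needs manual review and raise an "ambiguous annotation" error.
#'
#' @param record a `genome_record`.
#' @param dialects label patterns; see [ssu_dialects()].
#' @return the matching feature (list) or `NULL`.
#' @export
find_ssu_rrna <- function(record, dialects = ssu_dialects()) {
  stopifnot(inherits(record, "genome_record"))
  rrna <- Filter(function(f) identical(f$kind, "rRNA"), record$features)
  hit <- Filter(function(f) {
    any(vapply(dialects, function(d) grepl(d, f$label, ignore.case = TRUE, fixed = FALSE),
               logical(1L)))
  }, rrna)
  if (length(hit) == 0L) return(NULL)
  if (length(hit) > 1L)
    stop(sprintf("ambiguous annotation in %s: %d features match the SSU rRNA dialects",
                 record$accession, length(hit)), call. = FALSE)
  f <- hit[[1L]]
  if (isTRUE(f$compound))
    stop(sprintf("ambiguous annotation in %s: compound (join/order) rRNA location",
                 record$accession), call. = FALSE)
  f
}

#' Excise a gene feature from a genome record in gene orientation
#'
#' Returns the subsequence over the feature interval, reverse-complemented
#' when the feature lies on the minus strand, so the result always reads
#' 5'-to-3' along the gene. Lineage and provenance are carried along.
#'
#' @param record a `genome_record`.
#' @param feature one of the record's features (e.g. from [find_ssu_rrna()]).
#' @return an `excised_gene` object with fields `accession`, `organism`,
#'   `lineage`, `sequence`, `start`, `end`, `strand`, `length`, `status`
#'   (initially `"kept"`) and `reason`.
#' @export
excise_gene <- function(record, feature) {
  stopifnot(inherits(record, "genome_record"))
  stopifnot(feature$start >= 1L, feature$end <= record$length)
  seq <- substr(record$sequence, feature$start, feature$end)
  if (identical(feature$strand, "-")) seq <- reverse_complement(seq)
  structure(
    list(accession = record$accession, organism = record$organism,
         lineage = record$lineage, sequence = seq,
         start = feature$start, end = feature$end, strand = feature$strand,
         length = nchar(seq), status = "kept", reason = ""),
    class = "excised_gene"
  )
}

#' @export
print.excised_gene <- function(x, ...) {
  cat(sprintf("<excised_gene> %s  %d bp  [%d..%d](%s)  status=%s%s\n",
              x$accession, x$length, x$start, x$end, x$strand, x$status,
              if (nzchar(x$reason)) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

#' Validate an excised gene against length and ambiguity bounds
#'
#' Mirrors the curation step in which mis-annotated genes are dropped before
#' screening: genes shorter than `min_len`, longer than `max_len`, or with
#' more than `max_ambig_frac` non-ACGT characters are marked
#' `status = "removed"` with an explicit reason; others stay `"kept"`.
#' Defaults are deliberately loose bounds for a mitochondrial SSU rRNA.
#'
#' @param gene an `excised_gene`.
#' @param min_len,max_len accepted length range in bp.
#' @param max_ambig_frac maximal tolerated fraction of ambiguous bases.
#' @return the gene with `status`/`reason` updated.
#' @export
validate_excised <- function(gene, min_len = 300L, max_len = 2500L,
                             max_ambig_frac = 0.10) {
  stopifnot(inherits(gene, "excised_gene"), min_len < max_len)
  if (gene$length < min_len) {
    gene$status <- "removed"; gene$reason <- "too short"
  } else if (gene$length > max_len) {
    gene$status <- "removed"; gene$reason <- "too long"
  } else {
    n_ambig <- gene$length - sum(
      charToRaw(gene$sequence) %in% charToRaw("ACGT"))
    if (n_ambig / gene$length > max_ambig_frac) {
      gene$status <- "removed"; gene$reason <- "too many ambiguous bases"
    } else {
      gene$status <- "kept"; gene$reason <- ""
    }
  }
  gene
}

#' Write excised genes as FASTA plus a TSV manifest
#'
#' The FASTA holds only kept genes (header `accession|organism`); the
#' manifest lists every gene with its lineage, source interval, strand,
#' length, status and removal reason, in input order.
#'
#' @param genes list of `excised_gene` objects.
#' @param fasta,manifest output paths (either may be `NULL` to skip).
#' @return invisibly, the manifest data frame.
#' @export
write_excised <- function(genes, fasta = NULL, manifest = NULL) {
  man <- data.frame(
    accession = vapply(genes, `[[`, "", "accession"),
    organism  = vapply(genes, `[[`, "", "organism"),
    lineage   = vapply(genes, function(g) paste(g$lineage, collapse = "; "), ""),
    start     = vapply(genes, function(g) as.integer(g$start), 0L),
    end       = vapply(genes, function(g) as.integer(g$end), 0L),
    strand    = vapply(genes, `[[`, "", "strand"),
    length    = vapply(genes, function(g) as.integer(g$length), 0L),
    status    = vapply(genes, `[[`, "", "status"),
    reason    = vapply(genes, `[[`, "", "reason"),
    stringsAsFactors = FALSE
  )
  if (!is.null(fasta)) {
    kept <- Filter(function(g) g$status == "kept", genes)
    seqs <- Biostrings::DNAStringSet(vapply(kept, `[[`, "", "sequence"))
    names(seqs) <- vapply(kept, function(g) paste0(g$accession, "|", g$organism), "")
    Biostrings::writeXStringSet(seqs, fasta)
  }
  if (!is.null(manifest)) {
    utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(man)
}
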