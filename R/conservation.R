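# Conserved-region detection in a gapped multiple alignment and derivation
# of IUPAC-degenerate consensus primers.

#' Read a gapped FASTA alignment into an alignment matrix
#'
#' @param path aligned FASTA file (gap character `-`).
#' @return an `alignment_matrix`: list with `ids`, `rows` (uppercase gapped
#'   strings of equal length) and `n_cols`.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  alignment_matrix(as.character(ss), names(ss))
}

#' Construct an alignment matrix from gapped strings
#'
#' @param rows character vector of equal-length gapped sequences.
#' @param ids unique sequence identifiers.
#' @return an `alignment_matrix` object.
#' @export
alignment_matrix <- function(rows, ids = names(rows)) {
  rows <- toupper(unname(rows))
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  if (length(rows) < 2L) stop("alignment needs at least 2 rows", call. = FALSE)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  if (anyDuplicated(ids)) stop("alignment ids must be unique", call. = FALSE)
  structure(list(ids = ids, rows = rows, n_cols = nchar(rows[1L])),
            class = "alignment_matrix")
}

#' Per-column base composition of an alignment
#'
#' Counts A/C/G/T, other (ambiguity codes such as N) and gap characters per
#' column, and the majority base with its gap- and ambiguity-excluded
#' frequency. Ambiguous residues carry no positional information and are
#' excluded from the majority denominator. Ties break alphabetically.
#'
#' @param aln an `alignment_matrix`.
#' @return data frame with one row per column: `col`, `A`, `C`, `G`, `T`,
#'   `other`, `gap`, `majority_base`, `majority_freq`, `gap_fraction`.
#' @export
column_profiles <- function(aln) {
  stopifnot(inherits(aln, "alignment_matrix"))
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  n <- nrow(m)
  tab <- function(b) colSums(m == b)
  counts <- cbind(A = tab("A"), C = tab("C"), G = tab("G"), T = tab("T"),
                  gap = tab("-"))
  other <- n - rowSums(counts)
  base_counts <- counts[, c("A", "C", "G", "T"), drop = FALSE]
  denom <- rowSums(base_counts)
  maj_idx <- max.col(base_counts, ties.method = "first")  # columns are A<C<G<T
  maj_base <- colnames(base_counts)[maj_idx]
  maj_count <- base_counts[cbind(seq_len(nrow(base_counts)), maj_idx)]
  maj_freq <- ifelse(denom > 0, maj_count / denom, NA_real_)
  maj_base[denom == 0] <- NA_character_
  data.frame(
    col = seq_len(aln$n_cols),
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], T = counts[, "T"],
    other = other, gap = counts[, "gap"],
    majority_base = maj_base, majority_freq = maj_freq,
    gap_fraction = counts[, "gap"] / n,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Find conserved regions in an alignment
#'
#' A conserved region is a maximal run of consecutive columns that each have
#' majority-base frequency at least `min_majority_freq` and gap fraction at
#' most `max_gap_fraction`; runs shorter than `min_length` columns are not
#' reported. This is the alignment-scanning step of primer design: runs long
#' enough to hold an oligo become candidate primer sites.
#'
#' @param profiles output of [column_profiles()] (or an `alignment_matrix`,
#'   profiled on the fly).
#' @param min_length minimal region length in columns.
#' @param min_majority_freq conservation threshold in (0, 1].
#' @param max_gap_fraction maximal tolerated per-column gap fraction.
#' @return data frame of regions sorted by start: `start`, `end` (1-based
#'   inclusive alignment columns), `length`, `mean_majority_freq`.
#' @export
find_conserved_regions <- function(profiles, min_length = 20L,
                                   min_majority_freq = 0.75,
                                   max_gap_fraction = 0.10) {
  if (inherits(profiles, "alignment_matrix")) profiles <- column_profiles(profiles)
  stopifnot(min_length >= 1L,
            min_majority_freq > 0, min_majority_freq <= 1,
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  ok <- !is.na(profiles$majority_freq) &
    profiles$majority_freq >= min_majority_freq &
    profiles$gap_fraction <= max_gap_fraction
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep])
  out$mean_majority_freq <- vapply(seq_len(nrow(out)), function(i) {
    mean(profiles$majority_freq[out$start[i]:out$end[i]])
  }, numeric(1L))
  out[order(out$start), , drop = FALSE]
}

#' Derive an IUPAC-degenerate consensus primer over a conserved region
#'
#' Per column, the emitted IUPAC code covers every base whose gap- and
#' ambiguity-excluded frequency is at least `include_freq`, and always the
#' majority base. A reverse-orientation primer is emitted as the reverse
#' complement of the sense-strand consensus so it reads 5'-to-3' as a
#' synthesizable oligo.
#'
#' @param aln an `alignment_matrix`.
#' @param region one row of [find_conserved_regions()] output, or any list
#'   with `start` and `end` alignment columns (1-based inclusive).
#' @param include_freq inclusion threshold in (0, 0.5].
#' @param orientation `"forward"` or `"reverse"`.
#' @param name primer name.
#' @return a [primer()] object.
#' @export
degenerate_consensus <- function(aln, region, include_freq = 0.10,
                                 orientation = c("forward", "reverse"),
                                 name = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(include_freq > 0, include_freq <= 0.5)
  start <- as.integer(region$start[1L]); end <- as.integer(region$end[1L])
  stopifnot(start >= 1L, end <= aln$n_cols, start <= end)
  prof <- column_profiles(aln)[start:end, , drop = FALSE]
  codes <- vapply(seq_len(nrow(prof)), function(i) {
    cnt <- c(A = prof$A[i], C = prof$C[i], G = prof$G[i], T = prof$T[i])
    denom <- sum(cnt)
    if (denom == 0L)
      stop(sprintf("column %d has no unambiguous residues", prof$col[i]),
           call. = FALSE)
    sel <- names(cnt)[cnt / denom >= include_freq]
    sel <- union(sel, prof$majority_base[i])
    bits <- sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[sel])
    names(IUPAC_BITS)[match(bits, IUPAC_BITS)]
  }, character(1L))
  sense <- paste(codes, collapse = "")
  seq <- if (orientation == "reverse") reverse_complement(sense) else sense
  if (is.null(name))
    name <- sprintf("cons_%d_%d_%s", start, end,
                    if (orientation == "forward") "F" else "R")
  primer(name, seq, orientation)
}

#' Write designed primers and conserved regions to disk
#'
#' Emits a primer FASTA, a primer TSV (name, sequence, orientation, region
#' columns, degeneracy) and a BED-like region TSV in alignment coordinates.
#'
#' @param primers list of [primer()] objects.
#' @param regions data frame from [find_conserved_regions()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_design <- function(primers, regions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "primers.fasta"),
             tsv = file.path(dir, "primers.tsv"),
             bed = file.path(dir, "conserved_regions.tsv"))
  seqs <- Biostrings::BStringSet(vapply(primers, `[[`, "", "sequence"))
  names(seqs) <- vapply(primers, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, paths["fasta"])
  ptab <- data.frame(
    name = vapply(primers, `[[`, "", "name"),
    sequence = vapply(primers, `[[`, "", "sequence"),
    orientation = vapply(primers, `[[`, "", "orientation"),
    degeneracy = vapply(primers, function(p) p$degeneracy, numeric(1L)),
    stringsAsFactors = FALSE
  )
  utils::write.table(ptab, paths["tsv"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(regions, paths["bed"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
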