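# IUPAC-aware ungapped primer-site search, mismatch categorisation,
# 3'-anchored positional profiling and amplicon length prediction.
#
# Orientation convention: a reverse primer binds the minus strand, so its
# footprint on the target's sense strand is scanned with the primer's
# reverse complement. Position numbering in match flags and profiles starts
# at 1 from the primer's 3' end — the end that matters most for polymerase
# extension.

#' Best ungapped binding site of a primer on a target sequence
#'
#' Scans every ungapped offset and returns the site with the fewest
#' mismatches under IUPAC intersection semantics (an N in the target never
#' counts as a mismatch); ties break to the smallest offset. Reverse-oriented
#' primers are reverse-complemented before scanning, so the reported
#' footprint always lies on the target's sense strand.
#'
#' @param primer a [primer()] object (or IUPAC string, taken as forward).
#' @param target an `excised_gene`, or a plain IUPAC string; may also be a
#'   named list with `accession` and `sequence`.
#' @return a `primer_site_hit`: list with `target_id`, `primer_name`,
#'   `orientation`, `offset` (0-based start of the footprint on the sense
#'   strand), `footprint_length`, `mismatch_count`, `match_flags` (logical,
#'   position 1 = primer 3' end) and `aligned_target` (footprint read in
#'   primer orientation, 5'-to-3').
#' @export
best_site <- function(primer, target) {
  if (is.character(primer)) primer <- primer("primer", primer)
  tseq <- if (is.character(target)) target else target$sequence
  tid <- if (is.character(target)) "target" else target$accession
  L <- nchar(primer$sequence)
  if (nchar(tseq) < L)
    stop(sprintf("target %s (%d bp) shorter than primer %s (%d bp)",
                 tid, nchar(tseq), primer$name, L), call. = FALSE)
  scan_seq <- if (primer$orientation == "reverse")
    reverse_complement(primer$sequence) else primer$sequence
  res <- .scan_best_site(iupac_bits(scan_seq, "primer"),
                         iupac_bits(tseq, "target"))
  offset <- res[1L]
  footprint <- substr(tseq, offset + 1L, offset + L)
  # read the footprint in primer orientation and compare position-wise
  aligned <- if (primer$orientation == "reverse")
    reverse_complement(footprint) else footprint
  ok <- iupac_match(strsplit(aligned, "", fixed = TRUE)[[1L]],
                    strsplit(primer$sequence, "", fixed = TRUE)[[1L]])
  structure(
    list(target_id = tid, primer_name = primer$name,
         orientation = primer$orientation,
         offset = offset, footprint_length = L,
         mismatch_count = res[2L],
         match_flags = rev(ok),     # index 1 = 3' end
         aligned_target = aligned),
    class = "primer_site_hit"
  )
}

#' @export
print.primer_site_hit <- function(x, ...) {
  cat(sprintf(
    "<primer_site_hit> %s on %s: offset %d, %d mismatch(es)\n  flags 3'->5': %s\n",
    x$primer_name, x$target_id, x$offset, x$mismatch_count,
    paste(as.integer(x$match_flags), collapse = "")))
  invisible(x)
}

#' Three-way mismatch category of a binding site
#'
#' The screening classification: `no_mismatch` (0), `one_mismatch` (1),
#' `two_or_more` (>= 2), determined solely by the mismatch count.
#'
#' @param hit a `primer_site_hit`, or an integer mismatch count.
#' @return factor with levels `no_mismatch`, `one_mismatch`, `two_or_more`.
#' @export
categorize <- function(hit) {
  n <- if (inherits(hit, "primer_site_hit")) hit$mismatch_count else hit
  stopifnot(all(n >= 0))
  factor(
    ifelse(n == 0L, "no_mismatch", ifelse(n == 1L, "one_mismatch", "two_or_more")),
    levels = c("no_mismatch", "one_mismatch", "two_or_more")
  )
}

#' Positional match profile of a primer across a cohort of binding sites
#'
#' For each primer position counted from the 3' end, tallies the target base
#' observed under that position (read in primer orientation, so a reverse
#' primer's profile is over the strand it anneals to) and the fraction of
#' sites matching the primer code there. Positions whose match fraction
#' falls below `flag_threshold` are flagged as likely amplification risks.
#'
#' @param primer the [primer()] the hits belong to.
#' @param hits list of `primer_site_hit` objects for that primer.
#' @param flag_threshold flagging threshold on the match fraction.
#' @return data frame, one row per primer position: `position` (1 = 3' end),
#'   `primer_code`, counts `A`, `C`, `G`, `T`, `other`, `match_fraction`,
#'   `flagged`.
#' @export
positional_profile <- function(primer, hits, flag_threshold = 0.35) {
  if (length(hits) == 0L) stop("no hits to profile", call. = FALSE)
  bad <- vapply(hits, function(h) !identical(h$primer_name, primer$name), logical(1L))
  if (any(bad)) stop("hits belong to a different primer", call. = FALSE)
  L <- nchar(primer$sequence)
  # aligned_target read 5'->3' in primer orientation; 3' position p = char L-p+1
  mat <- do.call(rbind, lapply(hits, function(h)
    rev(strsplit(h$aligned_target, "", fixed = TRUE)[[1L]])))
  flags <- do.call(rbind, lapply(hits, `[[`, "match_flags"))
  pcode <- rev(strsplit(primer$sequence, "", fixed = TRUE)[[1L]])
  count <- function(b) colSums(mat == b)
  other <- nrow(mat) - (count("A") + count("C") + count("G") + count("T"))
  out <- data.frame(
    position = seq_len(L), primer_code = pcode,
    A = count("A"), C = count("C"), G = count("G"), T = count("T"),
    other = other,
    match_fraction = colMeans(flags),
    stringsAsFactors = FALSE
  )
  out$flagged <- out$match_fraction < flag_threshold
  out
}

#' Predict the amplicon implied by a forward and a reverse binding site
#'
#' The insert length is the number of bases strictly between the two primer
#' footprints on the sense strand (the "product without primers"
#' convention); the total length adds both footprints back. Footprints that
#' overlap or lie in the wrong order admit no amplification and raise an
#' error.
#'
#' @param fwd,rev `primer_site_hit` objects for the forward and reverse
#'   primer on the same target.
#' @return an `amplicon_prediction`: list with `target_id`, `insert_length`,
#'   `total_length`, plus both hits.
#' @export
predict_amplicon <- function(fwd, rev) {
  stopifnot(inherits(fwd, "primer_site_hit"), inherits(rev, "primer_site_hit"))
  insert <- rev$offset - (fwd$offset + fwd$footprint_length)
  if (insert < 0L)
    stop(sprintf("no amplifiable orientation on %s: reverse footprint starts before forward footprint ends",
                 fwd$target_id), call. = FALSE)
  structure(
    list(target_id = fwd$target_id,
         insert_length = insert,
         total_length = insert + fwd$footprint_length + rev$footprint_length,
         forward = fwd, reverse = rev),
    class = "amplicon_prediction"
  )
}

#' Screen a primer against a collection of targets
#'
#' Convenience wrapper: best site and category per target. Targets shorter
#' than the primer are returned with status `"excluded"` instead of a hit.
#'
#' @param primer a [primer()] object.
#' @param targets list of `excised_gene` objects (or named character vector
#'   of sequences).
#' @return list with `hits` (per-target `primer_site_hit` or `NULL`) and
#'   `table` (data frame: target_id, mismatch_count, category, status).
#' @export
screen_primer <- function(primer, targets) {
  if (is.character(targets)) {
    ids <- names(targets)
    targets <- lapply(seq_along(targets), function(i)
      list(accession = ids[i], sequence = targets[[i]]))
  }
  hits <- lapply(targets, function(t) {
    tryCatch(best_site(primer, t), error = function(e) NULL)
  })
  ok <- !vapply(hits, is.null, logical(1L))
  mm <- rep(NA_integer_, length(hits))
  mm[ok] <- vapply(hits[ok], `[[`, 0L, "mismatch_count")
  tab <- data.frame(
    target_id = vapply(targets, function(t) t$accession, ""),
    mismatch_count = mm,
    category = ifelse(ok, as.character(categorize(ifelse(is.na(mm), 0L, mm))), NA),
    status = ifelse(ok, "screened", "excluded"),
    stringsAsFactors = FALSE
  )
  list(hits = hits, table = tab)
}
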