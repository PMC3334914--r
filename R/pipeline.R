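# Workflow wrappers composing the modules into the two study pipelines:
# design (excise -> align externally -> find regions -> emit primers) and
# screen (excise -> match -> categorise -> report).

#' Excise and validate SSU rRNA genes from GenBank files
#'
#' Parses every record of the given GenBank flat files, locates the
#' small-subunit rRNA feature, excises it in gene orientation and validates
#' it. Records without a matching annotation, with an ambiguous annotation,
#' or failing validation are carried in the manifest as `removed` with an
#' explicit reason — the in-silico analogue of dropping mis-annotated
#' genomes from a screen.
#'
#' @param paths GenBank flat files (plain or gzip).
#' @param dialects SSU label patterns, see [ssu_dialects()].
#' @param min_len,max_len,max_ambig_frac validation bounds, see
#'   [validate_excised()].
#' @param out_fasta,out_manifest optional output paths.
#' @return list with `genes` (all `excised_gene` objects, kept and removed;
#'   removed entries may carry an empty sequence when nothing could be
#'   excised) and `manifest` (data frame).
#' @export
run_excise <- function(paths, dialects = ssu_dialects(),
                       min_len = 300L, max_len = 2500L, max_ambig_frac = 0.10,
                       out_fasta = NULL, out_manifest = NULL) {
  records <- unlist(lapply(paths, read_genbank), recursive = FALSE)
  genes <- lapply(records, function(rec) {
    feat <- tryCatch(find_ssu_rrna(rec, dialects), error = function(e) e)
    if (inherits(feat, "error")) {
      return(removed_stub(rec, "ambiguous annotation"))
    }
    if (is.null(feat)) {
      return(removed_stub(rec, "no SSU rRNA annotation"))
    }
    validate_excised(excise_gene(rec, feat),
                     min_len = min_len, max_len = max_len,
                     max_ambig_frac = max_ambig_frac)
  })
  manifest <- write_excised(genes, fasta = out_fasta, manifest = out_manifest)
  list(genes = genes, manifest = manifest)
}

removed_stub <- function(rec, reason) {
  structure(
    list(accession = rec$accession, organism = rec$organism,
         lineage = rec$lineage, sequence = "",
         start = NA_integer_, end = NA_integer_, strand = NA_character_,
         length = 0L, status = "removed", reason = reason),
    class = "excised_gene"
  )
}

#' Design a degenerate primer pair from an aligned FASTA
#'
#' Profiles the alignment, reports all conserved regions passing the
#' thresholds, and derives degenerate consensus primers from the first and
#' last suitable region: a forward primer from the most 5' region and a
#' reverse primer (reverse-complemented to synthesis orientation) from the
#' most 3' one, so the pair flanks the variable segment between them.
#'
#' @param alignment path to an aligned FASTA, or an `alignment_matrix`.
#' @param min_length,min_majority_freq,max_gap_fraction region thresholds,
#'   see [find_conserved_regions()].
#' @param include_freq consensus inclusion threshold, see
#'   [degenerate_consensus()].
#' @param out_dir optional directory for primer/region files
#'   (see [write_design()]).
#' @return list with `regions` (data frame) and `primers` (list of
#'   [primer()] objects; empty when fewer than one region is found, one
#'   forward primer when only one region exists).
#' @export
run_design <- function(alignment, min_length = 20L, min_majority_freq = 0.75,
                       max_gap_fraction = 0.10, include_freq = 0.10,
                       out_dir = NULL) {
  aln <- if (inherits(alignment, "alignment_matrix")) alignment
         else read_alignment(alignment)
  regions <- find_conserved_regions(column_profiles(aln),
                                    min_length = min_length,
                                    min_majority_freq = min_majority_freq,
                                    max_gap_fraction = max_gap_fraction)
  primers <- list()
  if (nrow(regions) >= 1L) {
    primers <- c(primers, list(
      degenerate_consensus(aln, regions[1L, ], include_freq, "forward",
                           name = "consF")))
  }
  if (nrow(regions) >= 2L) {
    primers <- c(primers, list(
      degenerate_consensus(aln, regions[nrow(regions), ], include_freq,
                           "reverse", name = "consR")))
  }
  if (!is.null(out_dir)) write_design(primers, regions, out_dir)
  list(regions = regions, primers = primers)
}

#' Screen a primer pair against a target collection
#'
#' Runs the best-site search of each primer independently against every
#' kept target, categorises mismatch counts (0 / 1 / 2+), builds the
#' taxonomy-grouped coverage table, 3'-anchored positional profiles, and —
#' for targets where the two footprints admit an amplicon — the predicted
#' insert-length summary.
#'
#' @param fwd,rev forward and reverse [primer()] objects.
#' @param targets list of `excised_gene` objects (e.g. from [run_excise()];
#'   entries with `status != "kept"` are excluded and listed).
#' @param rank taxonomic grouping rank passed to [screen_table()].
#' @param flag_threshold positional-profile flagging threshold.
#' @param band focal amplicon band in bp.
#' @param out_dir optional directory for report files
#'   (see [write_reports()]).
#' @return list with `results` (per-target data frame incl. lineage
#'   list-column, mismatch counts, categories, insert length), `table`
#'   (a [screen_table()]), `profiles` (named list of positional profiles),
#'   `lengths` (a [length_summary()] or `NULL`), `exclusions` (data frame).
#' @export
run_screen <- function(fwd, rev, targets, rank = 2L, flag_threshold = 0.35,
                       band = c(400L, 600L), out_dir = NULL) {
  stopifnot(inherits(fwd, "degenerate_primer"), inherits(rev, "degenerate_primer"),
            fwd$orientation == "forward", rev$orientation == "reverse")
  kept <- Filter(function(g) identical(g$status, "kept"), targets)
  dropped <- Filter(function(g) !identical(g$status, "kept"), targets)
  exclusions <- data.frame(
    accession = vapply(dropped, `[[`, "", "accession"),
    reason = vapply(dropped, `[[`, "", "reason"),
    stringsAsFactors = FALSE
  )
  rows <- vector("list", length(kept))
  fwd_hits <- vector("list", length(kept))
  rev_hits <- vector("list", length(kept))
  for (i in seq_along(kept)) {
    g <- kept[[i]]
    fh <- tryCatch(best_site(fwd, g), error = function(e) NULL)
    rh <- tryCatch(best_site(rev, g), error = function(e) NULL)
    if (is.null(fh) || is.null(rh)) {
      exclusions <- rbind(exclusions, data.frame(
        accession = g$accession, reason = "target shorter than primer",
        stringsAsFactors = FALSE))
      next
    }
    fwd_hits[[i]] <- fh; rev_hits[[i]] <- rh
    amp <- tryCatch(predict_amplicon(fh, rh), error = function(e) NULL)
    rows[[i]] <- data.frame(
      accession = g$accession,
      fwd_mismatch = fh$mismatch_count, rev_mismatch = rh$mismatch_count,
      fwd_category = as.character(categorize(fh)),
      rev_category = as.character(categorize(rh)),
      insert_length = if (is.null(amp)) NA_integer_ else amp$insert_length,
      stringsAsFactors = FALSE
    )
    rows[[i]]$lineage <- I(list(kept[[i]]$lineage))
  }
  ok <- !vapply(rows, is.null, logical(1L))
  results <- do.call(rbind, rows[ok])
  if (is.null(results) || nrow(results) == 0L)
    stop("no screenable targets", call. = FALSE)
  names(results$lineage) <- NULL
  tab <- screen_table(results, rank = rank,
                      primer_names = c("fwd", "rev"))
  profiles <- list()
  profiles[[fwd$name]] <- positional_profile(fwd, Filter(Negate(is.null), fwd_hits),
                                             flag_threshold)
  profiles[[rev$name]] <- positional_profile(rev, Filter(Negate(is.null), rev_hits),
                                             flag_threshold)
  lens <- results$insert_length[!is.na(results$insert_length)]
  lengths <- if (length(lens)) length_summary(lens, band = band) else NULL
  if (!is.null(out_dir)) {
    write_reports(tab, lengths, profiles, out_dir)
    if (nrow(exclusions))
      utils::write.table(exclusions, file.path(out_dir, "exclusions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(results = results, table = tab, profiles = profiles,
       lengths = lengths, exclusions = exclusions)
}
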