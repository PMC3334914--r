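# Taxonomy-grouped coverage tables and amplicon-length summaries.

resolve_rank <- function(lineage, rank) {
  if (is.numeric(rank)) {
    d <- as.integer(rank)
    if (d >= 1L && d <= length(lineage)) return(lineage[[d]])
    return(NA_character_)
  }
  nm <- names(lineage)
  if (!is.null(nm) && rank %in% nm) return(unname(lineage[[which(nm == rank)[1L]]]))
  # fallback: the lineage element immediately below a clade with this name
  i <- which(tolower(lineage) == tolower(rank))
  if (length(i) && i[1L] < length(lineage)) return(lineage[[i[1L] + 1L]])
  NA_character_
}

#' Build a taxonomy-grouped mismatch-category coverage table
#'
#' Groups screening results by the lineage element at a taxonomic rank and
#' tabulates, per group and per primer, the count and percentage of targets
#' in each mismatch category (0 / 1 / 2+). Rows follow first appearance in
#' the input, so feeding records in database-taxonomy order reproduces that
#' hierarchy; targets without the requested rank fall into `"unassigned"`.
#'
#' @param results data frame with one row per screened target, holding a
#'   list-column `lineage` (character vectors, optionally rank-named) and a
#'   `<name>_category` column per primer.
#' @param rank integer lineage depth (e.g. `2` for phylum under a
#'   kingdom-rooted lineage) or a rank/clade name.
#' @param primer_names names of the primers; default: inferred from
#'   `*_category` columns.
#' @return a `screen_table` data frame: `group`, `n`, then per primer
#'   `<name>_<category>_n` and `<name>_<category>_pct` (percentages to two
#'   decimals).
#' @export
screen_table <- function(results, rank = 2L, primer_names = NULL) {
  stopifnot(is.data.frame(results), "lineage" %in% names(results))
  if (is.null(primer_names)) {
    primer_names <- sub("_category$", "",
                        grep("_category$", names(results), value = TRUE))
  }
  if (length(primer_names) == 0L) stop("no *_category columns", call. = FALSE)
  grp <- vapply(results$lineage, resolve_rank, "", rank = rank)
  grp[is.na(grp) | !nzchar(grp)] <- "unassigned"
  groups <- unique(grp)
  cats <- c("no_mismatch", "one_mismatch", "two_or_more")
  rows <- lapply(groups, function(g) {
    sel <- results[grp == g, , drop = FALSE]
    row <- list(group = g, n = nrow(sel))
    for (p in primer_names) {
      cv <- factor(sel[[paste0(p, "_category")]], levels = cats)
      cnt <- as.integer(table(cv))
      pct <- round(100 * cnt / nrow(sel), 2)
      for (k in seq_along(cats)) {
        row[[paste0(p, "_", cats[k], "_n")]] <- cnt[k]
        row[[paste0(p, "_", cats[k], "_pct")]] <- pct[k]
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rank") <- rank
  attr(out, "primer_names") <- primer_names
  class(out) <- c("screen_table", "data.frame")
  out
}

#' @export
print.screen_table <- function(x, ...) {
  cat(sprintf("<screen_table> %d group(s), %d target(s), primers: %s\n",
              nrow(x), sum(x$n),
              paste(attr(x, "primer_names"), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Summarise predicted amplicon lengths
#'
#' Minimum, maximum, a histogram over fixed-width bins and the count inside
#' a focal band, computed over insert lengths (the product-without-primers
#' convention).
#'
#' @param preds list of `amplicon_prediction` objects, or a numeric vector
#'   of insert lengths.
#' @param band focal band `c(lo, hi)` in bp, inclusive.
#' @param bin_width histogram bin width in bp.
#' @return a `length_summary` list: `n`, `min`, `max`, `band`, `band_count`,
#'   `histogram` (data frame `bin_lo`, `bin_hi`, `count`).
#' @export
length_summary <- function(preds, band = c(400L, 600L), bin_width = 100L) {
  lens <- if (is.numeric(preds)) preds
          else vapply(preds, `[[`, 0L, "insert_length")
  if (length(lens) == 0L) stop("no amplicon predictions to summarise", call. = FALSE)
  stopifnot(length(band) == 2L, band[1L] <= band[2L], bin_width > 0)
  lo <- floor(min(lens) / bin_width) * bin_width
  hi <- ceiling((max(lens) + 1) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(lens, breaks = breaks, right = FALSE, plot = FALSE)
  structure(
    list(n = length(lens), min = min(lens), max = max(lens),
         band = band, band_count = sum(lens >= band[1L] & lens <= band[2L]),
         histogram = data.frame(bin_lo = breaks[-length(breaks)],
                                bin_hi = breaks[-1L], count = h$counts)),
    class = "length_summary"
  )
}

#' @export
print.length_summary <- function(x, ...) {
  cat(sprintf("<length_summary> n=%d, range %d-%d bp, %d of %d within [%d, %d] bp\n",
              x$n, x$min, x$max, x$band_count, x$n, x$band[1L], x$band[2L]))
  invisible(x)
}

#' Write screening reports to a directory
#'
#' Emits `screen_table.tsv` (coverage table), `length_summary.tsv`
#' (min/max/band plus histogram), and one `positional_profile_<primer>.tsv`
#' per profile, all with stable ordering and fixed decimal formatting so
#' repeated runs are byte-identical.
#'
#' @param table a [screen_table()].
#' @param summary a [length_summary()], or `NULL`.
#' @param profiles named list of [positional_profile()] data frames, or
#'   `NULL`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reports <- function(table, summary = NULL, profiles = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  tf <- file.path(dir, "screen_table.tsv")
  tab <- as.data.frame(table)
  pct <- grep("_pct$", names(tab))
  tab[pct] <- lapply(tab[pct], function(v) sprintf("%.2f", v))
  utils::write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, tf)
  if (!is.null(summary)) {
    sf <- file.path(dir, "length_summary.tsv")
    head <- sprintf("# n=%d min=%d max=%d band=[%d,%d] band_count=%d",
                    summary$n, summary$min, summary$max,
                    summary$band[1L], summary$band[2L], summary$band_count)
    writeLines(head, sf)
    suppressWarnings(
      utils::write.table(summary$histogram, sf, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
    paths <- c(paths, sf)
  }
  for (nm in names(profiles)) {
    pf <- file.path(dir, sprintf("positional_profile_%s.tsv", nm))
    prof <- profiles[[nm]]
    prof$match_fraction <- sprintf("%.4f", prof$match_fraction)
    utils::write.table(prof, pf, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pf)
  }
  invisible(paths)
}

#' Stacked-bar plot of a positional match profile
#'
#' Base-graphics rendering of the per-position base composition under a
#' primer, positions running 3' to 5' left to right; matching composition is
#' conveyed by the printed match fraction above each bar.
#'
#' @param profile a [positional_profile()] data frame.
#' @param main plot title.
#' @return invisibly, the bar midpoints.
#' @export
plot_positional_profile <- function(profile, main = "Positional profile") {
  m <- t(as.matrix(profile[, c("A", "C", "G", "T", "other")]))
  cols <- c(A = "forestgreen", C = "royalblue", G = "goldenrod",
            T = "firebrick", other = "grey70")
  mid <- graphics::barplot(m, names.arg = profile$position, col = cols,
                           border = NA, xlab = "position from 3' end",
                           ylab = "targets", main = main,
                           legend.text = rownames(m))
  graphics::text(mid, colSums(m) * 1.02,
                 labels = sprintf("%.2f", profile$match_fraction),
                 cex = 0.6, xpd = NA)
  invisible(mid)
}
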