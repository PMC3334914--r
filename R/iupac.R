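# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8). A gap or any
# character outside the 15-letter ambiguity alphabet has no mask and is
# rejected; two codes are compatible iff their masks intersect.

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  Y = 10L, S = 6L,  W = 9L,
  K = 12L, M = 3L,  B = 14L, D = 13L, H = 11L, V = 7L,
  N = 15L
)

# complement permutes the base bits: A<->T, C<->G
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
  N = "N"
)

#' Encode an IUPAC DNA string as a vector of 4-bit masks
#'
#' @param seq single uppercase-insensitive IUPAC string.
#' @param what label used in error messages.
#' @return integer vector of bit masks, one per character.
#' @keywords internal
iupac_bits <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bits <- unname(IUPAC_BITS[chars])
  if (anyNA(bits)) {
    bad <- unique(chars[is.na(bits)])
    stop(sprintf("non-IUPAC character(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  bits
}

#' Do two IUPAC codes share at least one concrete base?
#'
#' Intersection semantics: `iupac_match("A", "N")` is `TRUE`, and an `N` in a
#' target never scores as a mismatch against any primer code. Vectorised over
#' both arguments.
#'
#' @param target_base character vector of IUPAC codes seen in the target.
#' @param primer_code character vector of IUPAC codes from the primer.
#' @return logical vector: `TRUE` where the expansion sets intersect.
#' @examples
#' iupac_match("G", "R")  # TRUE,  R = {A,G}
#' iupac_match("C", "R")  # FALSE
#' @export
iupac_match <- function(target_base, primer_code) {
  tb <- unname(IUPAC_BITS[toupper(target_base)])
  pb <- unname(IUPAC_BITS[toupper(primer_code)])
  if (anyNA(tb) || anyNA(pb))
    stop("non-IUPAC character passed to iupac_match()", call. = FALSE)
  bitwAnd(tb, pb) > 0L
}

#' Reverse-complement an IUPAC DNA string
#'
#' Every ambiguity code is complemented under the standard map
#' (A-T, C-G, R-Y, K-M, B-V, D-H; S, W, N are self-complementary) and the
#' string is reversed. The empty string maps to itself.
#'
#' @param seq single IUPAC DNA string.
#' @return the reverse complement, uppercase.
#' @examples
#' reverse_complement("AACC")  # "GGTT"
#' reverse_complement("RN")    # "NY"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(seq)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  comp <- unname(IUPAC_COMPLEMENT[chars])
  if (anyNA(comp)) {
    bad <- unique(chars[is.na(comp)])
    stop(sprintf("non-IUPAC character(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  paste(rev(comp), collapse = "")
}

#' Expand an IUPAC code to its set of concrete bases
#'
#' @param code single IUPAC character.
#' @return character vector drawn from A, C, G, T.
#' @export
iupac_expand <- function(code) {
  b <- iupac_bits(code, "code")
  c("A", "C", "G", "T")[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Degeneracy of an IUPAC primer string
#'
#' The number of concrete oligonucleotides a degenerate synthesis covers:
#' the product over positions of the expansion-set sizes.
#'
#' @param primer a [primer()] object or a plain IUPAC string.
#' @return integer (may be large; returned as double beyond int range).
#' @examples
#' degeneracy("ACGT")  # 1
#' degeneracy("NN")    # 16
#' @export
degeneracy <- function(primer) {
  seq <- if (inherits(primer, "degenerate_primer")) primer$sequence else primer
  bits <- iupac_bits(seq, "primer")
  if (length(bits) == 0L) return(1)
  sizes <- rowSums(outer(bits, c(1L, 2L, 4L, 8L), bitwAnd) > 0L)
  prod(sizes)
}

#' Construct a degenerate primer object
#'
#' A named IUPAC string written 5'-to-3' with an orientation. Reverse-oriented
#' primers are stored as synthesised (their footprint on a target's sense
#' strand is the reverse complement of this string).
#'
#' @param name primer name, e.g. `"12SF"`.
#' @param sequence IUPAC string, 5'-to-3'.
#' @param orientation `"forward"` or `"reverse"`.
#' @return object of class `degenerate_primer` with fields `name`,
#'   `sequence`, `orientation`, `degeneracy`.
#' @export
primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("primer sequence must be non-empty", call. = FALSE)
  iupac_bits(sequence, "primer")  # validates alphabet
  structure(
    list(name = name, sequence = sequence, orientation = orientation,
         degeneracy = degeneracy(sequence)),
    class = "degenerate_primer"
  )
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s)\n  5'-%s-3'  length %d, degeneracy %s\n",
              x$name, x$orientation, x$sequence, nchar(x$sequence),
              format(x$degeneracy, big.mark = ",")))
  invisible(x)
}
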