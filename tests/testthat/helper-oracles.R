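# Independent oracles. Deliberately built on Biostrings::IUPAC_CODE_MAP and
# character-set operations, not on the package's bit encoding, so the two
# routes can disagree if either is wrong.

IUPAC_CHARS <- names(Biostrings::IUPAC_CODE_MAP)  # 15 codes

oracle_expand <- function(code) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[toupper(code)]], "", fixed = TRUE)[[1L]]
}

# 15x15 logical lookup: do the expansion sets intersect?
ORACLE_MATCH <- {
  m <- matrix(FALSE, 15L, 15L, dimnames = list(IUPAC_CHARS, IUPAC_CHARS))
  for (a in IUPAC_CHARS) for (b in IUPAC_CHARS)
    m[a, b] <- length(intersect(oracle_expand(a), oracle_expand(b))) > 0L
  m
}

# Brute-force minimum-Hamming scan with set-intersection matching.
oracle_best_site <- function(primer_seq, target_seq) {
  pc <- strsplit(toupper(primer_seq), "", fixed = TRUE)[[1L]]
  tc <- strsplit(toupper(target_seq), "", fixed = TRUE)[[1L]]
  L <- length(pc)
  n_off <- length(tc) - L + 1L
  stopifnot(n_off >= 1L)
  win <- embed(seq_along(tc), L)[, L:1, drop = FALSE]  # row o = o..o+L-1
  ok <- ORACLE_MATCH[cbind(tc[as.vector(win)], rep(pc, each = n_off))]
  mm <- rowSums(!matrix(ok, nrow = n_off))
  list(offset = which.min(mm) - 1L, mismatch_count = as.integer(min(mm)))
}

# Degeneracy by exhaustive enumeration of concrete expansions.
oracle_degeneracy <- function(seq) {
  sets <- lapply(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], oracle_expand)
  nrow(unique(expand.grid(sets, stringsAsFactors = FALSE)))
}

random_iupac <- function(n, chars = IUPAC_CHARS) {
  paste(sample(chars, n, replace = TRUE), collapse = "")
}

random_acgt <- function(n) random_iupac(n, chars = c("A", "C", "G", "T"))
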