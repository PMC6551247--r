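# Amino-acid alphabet, integer encoding and scoring matrices shared by the
# index, graph and alignment layers.

# Canonical 20 residues; 'X' marks ambiguous residues and is kept in read
# sequences but never matched by FM-index patterns nor indexed as a seed.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

SENTINEL <- "$"

# BWT alphabet in lexicographic (ASCII) order: the sentinel sorts below every
# residue, and 'X' falls between 'W' and 'Y' exactly as the radix string sort
# used for suffix ordering sees it. Codes are 0 ($) .. 21.
BWT_ALPHABET <- c(SENTINEL, sort(c(AA20, "X")))

.pkg_cache <- new.env(parent = emptyenv())

#' @keywords internal
aa_regex <- function() "^[ACDEFGHIKLMNPQRSTVWYX]+$"

#' Validate peptide read sequences
#'
#' Checks that every sequence is non-empty and drawn from the 20 canonical
#' amino acids plus 'X'. The offending read is named in the error message.
#'
#' @param seqs character vector of peptide sequences.
#' @param ids optional read identifiers used in error messages.
#' @return invisibly, `seqs`.
#' @keywords internal
validate_peptides <- function(seqs, ids = NULL) {
  if (length(seqs) == 0L) stop("read set is empty")
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  bad <- which(is.na(seqs) | nchar(seqs) == 0L | !grepl(aa_regex(), seqs))
  if (length(bad) > 0L) {
    stop("read '", ids[bad[1L]],
         "' contains characters outside the amino-acid alphabet (or is empty)")
  }
  if (anyDuplicated(ids)) stop("read ids are not unique")
  invisible(seqs)
}

# Fast char -> code lookup (code 0 = sentinel). Indexed by raw byte value.
.char_code_table <- function() {
  if (is.null(.pkg_cache$code_tab)) {
    tab <- rep(NA_integer_, 256L)
    tab[utf8ToInt(SENTINEL) + 1L] <- 0L
    for (i in seq_along(BWT_ALPHABET)[-1L]) {
      tab[utf8ToInt(BWT_ALPHABET[i]) + 1L] <- i - 1L
    }
    .pkg_cache$code_tab <- tab
  }
  .pkg_cache$code_tab
}

#' Encode a peptide string as integer codes
#'
#' @param s single character string.
#' @return integer vector; sentinel = 0, residues follow ASCII order.
#' @keywords internal
encode_peptide <- function(s) {
  .char_code_table()[utf8ToInt(s) + 1L]
}

#' BLOSUM62 substitution matrix over the package alphabet
#'
#' Returns the Biostrings BLOSUM62 matrix restricted and reordered to the 20
#' canonical residues plus 'X', as an integer matrix whose row/column order
#' matches [BWT_ALPHABET] minus the sentinel.
#'
#' @return 21 x 21 integer matrix.
#' @export
blosum62_matrix <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    letters21 <- BWT_ALPHABET[-1L]
    m <- env$BLOSUM62[letters21, letters21]
    storage.mode(m) <- "integer"
    .pkg_cache$blosum62 <- m
  }
  .pkg_cache$blosum62
}

# Residue-code (1..21) indexed score lookup: square integer matrix whose
# [i, j] entry scores codes i and j (codes as produced by encode_peptide).
.score_by_code <- function() {
  if (is.null(.pkg_cache$score_code)) {
    .pkg_cache$score_code <- blosum62_matrix()  # already in code order
  }
  .pkg_cache$score_code
}

#' Score a pair of equal-length peptide segments, ungapped
#'
#' @param a,b equal-length peptide strings.
#' @return integer vector of per-position BLOSUM62 scores.
#' @keywords internal
pair_scores <- function(a, b) {
  ca <- encode_peptide(a)
  cb <- encode_peptide(b)
  stopifnot(length(ca) == length(cb))
  .score_by_code()[cbind(ca, cb)]
}

# Murphy-style 10-group reduced alphabet (as used for seeding by fast protein
# search tools); optional for seed indexing, exact alphabet is the default.
REDUCED10 <- c(
  A = "A", S = "A", T = "A",
  C = "C",
  D = "D", N = "D",
  E = "E", Q = "E",
  F = "F", W = "F", Y = "F",
  G = "G",
  H = "H",
  I = "I", L = "I", M = "I", V = "I",
  K = "K", R = "K",
  P = "P"
)

#' Reduce a peptide string to the 10-letter seeding alphabet
#' @param s peptide string ('X' is preserved).
#' @return reduced string.
#' @keywords internal
reduce_alphabet <- function(s) {
  chartr(paste(names(REDUCED10), collapse = ""),
         paste(REDUCED10, collapse = ""), s)
}

# Background amino-acid frequencies (SwissProt-like averages) used by the
# community simulator.
AA_BACKGROUND_FREQ <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0138,
  Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
  L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
  S = 0.0656, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687
)
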