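# Blockwise multi-string BWT / FM-index over peptide reads.
#
# Each read is terminated by its own sentinel; sentinels sort below every
# residue and ties between sentinel-terminated suffixes are broken by read
# order (the suffix sort is stable), so construction is fully deterministic.
# Rank (occ) tables are dense cumulative counts: memory is O(|alphabet| x
# total residues) per block, adequate for the reference scale this package
# targets; the block size bounds that footprint.

#' Partition reads into blocks and build per-block BWT/FM-index structures
#'
#' Reads are assigned to blocks in input order (`block_size` reads per block,
#' last block possibly smaller). Each block holds a multi-string BWT over its
#' member reads, the cumulative count (C) array, dense rank tables, and full
#' suffix-array samples mapping every BWT row to (read index, offset).
#'
#' @param reads character vector of peptide sequences (20 canonical residues
#'   plus 'X').
#' @param block_size maximum number of reads per block (default 100000).
#' @param ids optional read identifiers (used for error reporting only; blocks
#'   index reads by their global integer position).
#' @return list of `bwt_block` objects.
#' @examples
#' blocks <- build_blocks(c("MKVLITAAG", "TAAGHLKWQ"), block_size = 10)
#' backward_search(blocks[[1]], "TAAG")$width
#' @export
build_blocks <- function(reads, block_size = 100000L, ids = NULL) {
  validate_peptides(reads, ids)
  if (length(block_size) != 1L || is.na(block_size) || block_size < 1L) {
    stop("block_size must be a single integer >= 1")
  }
  block_of <- ceiling(seq_along(reads) / block_size)
  idx_by_block <- split(seq_along(reads), block_of)
  lapply(seq_along(idx_by_block), function(b) {
    build_bwt_block(b, idx_by_block[[b]], reads[idx_by_block[[b]]])
  })
}

#' Build a single multi-string BWT block
#'
#' @param block_id integer block label.
#' @param read_index global indices of the member reads.
#' @param seqs member read sequences, same order as `read_index`.
#' @return a `bwt_block`: bwt codes, C array, cumulative rank table,
#'   suffix-array samples (`sa_read` local read number, `sa_off` 0-based
#'   suffix offset) and sentinel row positions.
#' @keywords internal
build_bwt_block <- function(block_id, read_index, seqs) {
  n <- length(seqs)
  lens <- nchar(seqs)
  # all suffixes of every read, each terminated by the read's own sentinel;
  # offset L is the bare sentinel suffix
  suf_str <- vector("list", n)
  for (j in seq_len(n)) {
    L <- lens[j]
    suf_str[[j]] <- c(paste0(substring(seqs[j], seq_len(L), L), SENTINEL),
                      SENTINEL)
  }
  suf_str <- unlist(suf_str, use.names = FALSE)
  suf_read <- rep(seq_len(n), lens + 1L)
  suf_off <- sequence(lens + 1L) - 1L
  # stable radix sort: equal suffixes keep read order, which realizes the
  # "sentinel rank = read index" tie rule
  ord <- order(suf_str, method = "radix")
  sa_read <- suf_read[ord]
  sa_off <- suf_off[ord]

  # BWT character of row r = character preceding the suffix (the read's
  # sentinel for offset-0 suffixes)
  flat <- encode_peptide(paste(seqs, collapse = ""))
  start <- c(0L, cumsum(lens))[seq_len(n)]  # 0-based start of read j in flat
  bwt <- integer(length(sa_read))
  inner <- sa_off > 0L
  bwt[inner] <- flat[start[sa_read[inner]] + sa_off[inner]]

  nsym <- length(BWT_ALPHABET)
  counts <- tabulate(bwt + 1L, nbins = nsym)
  c_array <- cumsum(c(0L, counts))[seq_len(nsym)]  # chars strictly smaller
  occ <- matrix(0L, nrow = length(bwt) + 1L, ncol = nsym)
  for (k in which(counts > 0L)) {
    occ[, k] <- c(0L, cumsum(bwt == (k - 1L)))
  }
  structure(list(
    block_id = block_id,
    read_index = as.integer(read_index),
    lens = lens,
    n_reads = n,
    bwt = bwt,
    c_array = c_array,
    occ = occ,
    sa_read = sa_read,
    sa_off = sa_off,
    sent_rows = which(bwt == 0L)
  ), class = "bwt_block")
}

#' @export
print.bwt_block <- function(x, ...) {
  cat("bwt_block", x$block_id, "-", x$n_reads, "reads,",
      length(x$bwt), "BWT rows\n")
  invisible(x)
}

#' FM-index backward search
#'
#' Finds the half-open BWT row interval of all suffixes starting with
#' `pattern`; its width is the number of occurrences of `pattern` as a
#' substring across the block's reads. Patterns containing 'X' (or any
#' non-canonical character) match nothing by definition.
#'
#' @param block a `bwt_block`.
#' @param pattern non-empty amino-acid string.
#' @return list with `lower`, `upper` (0-based half-open row range) and
#'   `width`.
#' @export
backward_search <- function(block, pattern) {
  if (!inherits(block, "bwt_block")) stop("not a bwt_block")
  if (length(pattern) != 1L || is.na(pattern) || nchar(pattern) == 0L) {
    stop("pattern must be a non-empty string")
  }
  codes <- encode_peptide(pattern)
  xcode <- match("X", BWT_ALPHABET) - 1L
  if (anyNA(codes) || any(codes == 0L) || any(codes == xcode)) {
    return(list(lower = 0L, upper = 0L, width = 0L))
  }
  lo <- 0L
  hi <- length(block$bwt)
  for (c in rev(codes)) {
    lo <- block$c_array[c + 1L] + block$occ[lo + 1L, c + 1L]
    hi <- block$c_array[c + 1L] + block$occ[hi + 1L, c + 1L]
    if (lo >= hi) return(list(lower = 0L, upper = 0L, width = 0L))
  }
  list(lower = lo, upper = hi, width = hi - lo)
}

#' Locate the occurrences in an FM-index interval
#'
#' @param block a `bwt_block`.
#' @param interval result of [backward_search()].
#' @return data.frame with one row per interval element: `read` (global read
#'   index) and `offset` (0-based occurrence start within the read).
#' @export
fm_locate <- function(block, interval) {
  lo <- interval$lower
  hi <- interval$upper
  if (is.null(lo) || is.null(hi) || lo < 0L || hi > length(block$bwt) ||
      lo > hi) {
    stop("interval out of range for this block")
  }
  if (lo == hi) {
    return(data.frame(read = integer(0), offset = integer(0)))
  }
  rows <- (lo + 1L):hi
  data.frame(read = block$read_index[block$sa_read[rows]],
             offset = block$sa_off[rows])
}

#' Invert a block's BWT back into its member reads
#'
#' Walks the LF mapping from each sentinel row; used to check the invariant
#' that the index losslessly encodes its reads.
#'
#' @param block a `bwt_block`.
#' @return character vector of the member reads, in member order.
#' @export
invert_bwt <- function(block) {
  letters_by_code <- BWT_ALPHABET
  out <- character(block$n_reads)
  for (i in seq_len(block$n_reads)) {
    # the i-th smallest row is the bare-sentinel suffix of member read i
    row <- i
    chars <- integer(0)
    repeat {
      c <- block$bwt[row]
      if (c == 0L) break
      chars <- c(c, chars)
      row <- block$c_array[c + 1L] + block$occ[row + 1L, c + 1L]
    }
    out[i] <- paste(letters_by_code[chars + 1L], collapse = "")
  }
  out
}
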