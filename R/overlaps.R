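# Maximal suffix-prefix overlap and containment detection over BWT blocks.
#
# For every read, its suffixes are extended by backward search against every
# block; rows whose BWT character is the sentinel mark reads whose *prefix*
# equals the current suffix, so growing the suffix and keeping the last hit
# per target yields the maximal overlap for each ordered read pair. Only
# proper overlaps (shorter than both reads) are kept: full-length matches are
# containment-type. Containments (one read a substring of another) are only
# detected within a block -- a read pair split across blocks keeps both reads
# in the graph, and the resulting redundancy is rectified downstream by
# bubble removal and tip trimming.

#' Detect maximal suffix-prefix overlaps and within-block containments
#'
#' @param blocks list of `bwt_block` objects covering the read set.
#' @param reads the full read set (global indexing must match the blocks).
#' @param l minimum overlap length in residues (default 10).
#' @return list with `overlaps` (data.frame: source, target, length -- one row
#'   per ordered pair, maximal length only) and `containments` (data.frame:
#'   contained, container, offset). Exact duplicate reads resolve with the
#'   lower read index as container.
#' @export
find_overlaps <- function(blocks, reads, l = 10L) {
  if (l < 1L) stop("l must be >= 1")
  lens <- nchar(reads)
  if (l > max(lens)) {
    warning("minimum overlap l exceeds every read length; no overlaps")
    return(list(
      overlaps = data.frame(source = integer(0), target = integer(0),
                            length = integer(0)),
      containments = data.frame(contained = integer(0),
                                container = integer(0), offset = integer(0))
    ))
  }
  src <- integer(0); tgt <- integer(0); olen <- integer(0)
  for (i in seq_along(reads)) {
    codes <- rev(encode_peptide(reads[i]))  # fed from read end backwards
    L <- lens[i]
    if (L <= l) next  # a proper overlap needs l < L
    # per-target best overlap across all blocks
    best <- new.env(parent = emptyenv())
    for (blk in blocks) {
      lo <- 0L
      hi <- length(blk$bwt)
      occ <- blk$occ
      c_arr <- blk$c_array
      for (m in seq_len(L)) {       # suffix length after this step
        c <- codes[m]
        lo <- c_arr[c + 1L] + occ[lo + 1L, c + 1L]
        hi <- c_arr[c + 1L] + occ[hi + 1L, c + 1L]
        if (lo >= hi) break
        if (m < l || m == L) next   # proper overlap only: l <= m < L
        nsent <- occ[hi + 1L, 1L] - occ[lo + 1L, 1L]
        if (nsent == 0L) next
        srange <- findInterval(c(lo, hi), blk$sent_rows)  # sent_rows sorted
        rows <- blk$sent_rows[(srange[1L] + 1L):srange[2L]]
        hits <- blk$read_index[blk$sa_read[rows]]
        for (t in hits) {
          if (t == i) next
          if (m >= lens[t]) next    # target fully matched => containment-type
          assign(as.character(t), m, envir = best)  # larger m overwrites
        }
      }
    }
    tnames <- ls(best)
    if (length(tnames) > 0L) {
      src <- c(src, rep(i, length(tnames)))
      tgt <- c(tgt, as.integer(tnames))
      olen <- c(olen, vapply(tnames, get, integer(1), envir = best))
    }
  }
  ov <- data.frame(source = src, target = tgt, length = olen)
  ov <- ov[order(ov$source, ov$target), , drop = FALSE]
  rownames(ov) <- NULL

  cont <- find_containments(blocks, reads)
  list(overlaps = ov, containments = cont)
}

# Within-block containment scan: each read's full sequence is searched in its
# own block; occurrences inside longer reads (or equal-length duplicates,
# lower index wins as container) are containments.
#' @keywords internal
find_containments <- function(blocks, reads) {
  lens <- nchar(reads)
  contained <- integer(0); container <- integer(0); offset <- integer(0)
  for (blk in blocks) {
    for (j in seq_len(blk$n_reads)) {
      g <- blk$read_index[j]
      iv <- backward_search(blk, reads[g])
      if (iv$width <= 1L && lens[g] > 0L) next  # only the self occurrence
      occs <- fm_locate(blk, iv)
      occs <- occs[occs$read != g, , drop = FALSE]
      if (nrow(occs) == 0L) next
      keep <- lens[occs$read] > lens[g] |
        (lens[occs$read] == lens[g] & occs$read < g)
      occs <- occs[keep, , drop = FALSE]
      if (nrow(occs) == 0L) next
      # deterministic single container: smallest container index, then offset
      occs <- occs[order(occs$read, occs$offset), , drop = FALSE]
      contained <- c(contained, g)
      container <- c(container, occs$read[1L])
      offset <- c(offset, occs$offset[1L])
    }
  }
  out <- data.frame(contained = contained, container = container,
                    offset = offset)
  out <- out[order(out$contained), , drop = FALSE]
  rownames(out) <- NULL
  out
}
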