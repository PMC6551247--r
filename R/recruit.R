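# Read recruitment: map the original short-peptide reads onto assembled
# homologous contigs, mirroring the search stage (exact k-mer seeds against
# the contig set, then banded gapped verification).

#' Recruit reads onto homologous contigs
#'
#' A read is recruited when some seeded, banded alignment against a contig
#' reaches `min_identity` (matches / alignment columns) over at least
#' `min_span` of the read length, and the placement overlaps the contig's
#' homologous interval (the region the reference aligned to, columns
#' `s_lo`/`s_hi` of the contig table) by more than `min_hit_overlap` of the
#' read length -- candidate paths are spelled slightly longer than the
#' reference, and reads on the non-homologous flanks are not homolog calls.
#' Each read is assigned to at most one (query, contig): the contig with the
#' most significant E-value wins, ties go to the smaller query id, then to the
#' higher identity, then to (contig_id, position).
#'
#' @param contigs contig data.frame from [assemble_homologs()] (possibly
#'   rbind-ed across queries).
#' @param reads character vector of reads.
#' @param read_ids read identifiers.
#' @param min_identity identity threshold in `[0,1]` (default 0.9).
#' @param min_span minimum aligned fraction of the read length (default 0.8).
#' @param min_hit_overlap minimum fraction of the read length overlapping the
#'   contig's homologous interval (default 0.6).
#' @param k seed length (default 6).
#' @param gap_open,gap_extend affine gap penalties for verification.
#' @return data.frame: read_id, query_id, contig_id, pos (0-based contig
#'   position), identity, evalue.
#' @export
recruit <- function(contigs, reads, read_ids = NULL,
                    min_identity = 0.9, min_span = 0.8,
                    min_hit_overlap = 0.6, k = 6L,
                    gap_open = 11L, gap_extend = 1L) {
  if (is.null(read_ids)) read_ids <- paste0("read", seq_along(reads))
  empty <- data.frame(read_id = character(0), query_id = character(0),
                      contig_id = character(0), pos = integer(0),
                      identity = numeric(0), evalue = numeric(0))
  if (is.null(contigs) || nrow(contigs) == 0L) return(empty)
  cidx <- index_seeds(contigs$sequence, k = k)
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    sm <- seed_matches(cidx, reads[i])
    if (nrow(sm) == 0L) next
    cand <- split(sm, sm$unitig_id)
    placements <- list()
    for (cs in cand) {
      cid <- cs$unitig_id[1L]
      diags <- cs$query_pos - cs$unitig_pos
      center <- as.integer(round((min(diags) + max(diags)) / 2))
      width <- as.integer((max(diags) - min(diags)) / 2) + 6L
      aln <- banded_smith_waterman(reads[i], contigs$sequence[cid],
                                   band_width = width, band_center = center,
                                   gap_open = gap_open,
                                   gap_extend = gap_extend)
      if (aln$align_cols == 0L) next
      identity <- aln$nmatch / aln$align_cols
      span <- (aln$q_hi - aln$q_lo) / nchar(reads[i])
      hom_ovl <- (min(contigs$s_hi[cid], aln$s_hi) -
                    max(contigs$s_lo[cid], aln$s_lo)) / nchar(reads[i])
      if (identity >= min_identity && span >= min_span &&
          hom_ovl > min_hit_overlap) {
        placements[[length(placements) + 1L]] <- data.frame(
          read_id = read_ids[i], query_id = contigs$query_id[cid],
          contig_id = contigs$contig_id[cid],
          pos = aln$s_lo - aln$q_lo,  # contig start implied by the alignment
          identity = identity, evalue = contigs$evalue[cid])
      }
    }
    if (length(placements) == 0L) next
    pl <- do.call(rbind, placements)
    pl <- pl[order(pl$evalue, pl$query_id, -pl$identity, pl$contig_id,
                   pl$pos), , drop = FALSE]
    out[[i]] <- pl[1L, , drop = FALSE]
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Direct per-read seeded search (comparator)
#'
#' BLAST-like per-read homolog search used as the sensitivity baseline: a read
#' is reported iff it shares at least one exact k-mer with the query and its
#' banded alignment against the query passes the E-value cutoff. Reads lacking
#' any shared seed with the query are invisible to this search by
#' construction, which is exactly the failure mode assembly-mediated
#' recruitment repairs.
#'
#' @param query reference protein sequence.
#' @param reads,read_ids the read set.
#' @param k seed length (default 6).
#' @param evalue_cutoff acceptance cutoff (default 1e-3).
#' @param lambda,K Karlin-Altschul parameters.
#' @param query_id label for the output.
#' @return data.frame: read_id, query_id, score, evalue.
#' @export
direct_read_search <- function(query, reads, read_ids = NULL, k = 6L,
                               evalue_cutoff = 1e-3, lambda = 0.267,
                               K = 0.041, query_id = "query") {
  if (is.null(read_ids)) read_ids <- paste0("read", seq_along(reads))
  qidx <- index_seeds(query, k = k)
  db <- sum(nchar(reads))
  hits <- list()
  for (i in seq_along(reads)) {
    sm <- seed_matches(qidx, reads[i])
    if (nrow(sm) == 0L) next
    aln <- banded_smith_waterman(reads[i], query)
    ev <- evalue_of(aln$score, nchar(query), db, lambda = lambda, K = K)
    if (ev <= evalue_cutoff) {
      hits[[length(hits) + 1L]] <- data.frame(
        read_id = read_ids[i], query_id = query_id,
        score = aln$score, evalue = ev)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(read_id = character(0), query_id = character(0),
                      score = integer(0), evalue = numeric(0)))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
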