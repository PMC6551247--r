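# End-to-end index construction and homolog assembly.

#' Build the full GRASP2 index over a peptide read set
#'
#' Runs the indexing stage: blockwise BWT construction, maximal-overlap and
#' containment detection, string-graph construction and cleanup, unitig
#' collapsing and seed indexing.
#'
#' @param reads character vector of peptide reads.
#' @param ids read identifiers (default `read1..readN`).
#' @param config a [grasp_config()] list; individual fields can be overridden
#'   via `...`.
#' @param ... overrides passed to [grasp_config()].
#' @return a `grasp2_index`: reads, ids, blocks, overlaps, containments,
#'   graph (cleaned), unitigs (`unitig_graph`), seed index, `db_residues`,
#'   config.
#' @export
grasp_index <- function(reads, ids = NULL, config = grasp_config(...), ...) {
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  validate_peptides(reads, ids)
  blocks <- build_blocks(reads, block_size = config$block_size, ids = ids)
  ovc <- find_overlaps(blocks, reads, l = config$l)
  sg <- build_graph(ovc$overlaps, ovc$containments, reads)
  sg <- clean_graph(sg, depth = config$bubble_depth,
                    transitive = config$transitive_reduction)
  ug <- collapse_unitigs(sg)
  sidx <- index_seeds(ug, k = config$k, reduced = config$reduced_alphabet)
  structure(list(reads = reads, ids = ids, blocks = blocks,
                 overlaps = ovc$overlaps, containments = ovc$containments,
                 graph = sg, unitigs = ug, seed_index = sidx,
                 db_residues = sum(nchar(reads)), config = config),
            class = "grasp2_index")
}

#' @export
print.grasp2_index <- function(x, ...) {
  cat("grasp2_index:", length(x$reads), "reads in", length(x$blocks),
      "block(s);", nrow(x$unitigs$unitigs), "unitigs,",
      nrow(x$unitigs$links), "links\n")
  invisible(x)
}

#' Band half-width rule for candidate-path alignment
#' @param query_length reference length in residues.
#' @return integer band half-width, `max(40, ceil(0.2 * query_length))`.
#' @export
band_width_rule <- function(query_length) {
  max(40L, as.integer(ceiling(0.2 * query_length)))
}

#' Assemble homologous contigs for one reference protein
#'
#' The full search stage: seeded ungapped extension selects anchor unitigs,
#' anchor-ordered DFS spells candidate paths, banded Smith-Waterman scores
#' each path against the reference, and paths passing the E-value cutoff are
#' emitted as homologous contigs sorted by E-value.
#'
#' @param query reference protein sequence.
#' @param index a `grasp2_index`.
#' @param query_id label used in the output (default "query").
#' @return data.frame of contigs: contig_id, query_id, path (comma-joined
#'   unitig walk), sequence (full spelled path), score, evalue, q_lo, q_hi,
#'   s_lo, s_hi, edit, nmatch, align_cols. Zero rows when nothing passes.
#' @export
assemble_homologs <- function(query, index, query_id = "query") {
  cfg <- index$config
  ug <- index$unitigs
  anchors <- compute_anchors(index$seed_index, ug$unitigs$sequence, query,
                             xdrop = cfg$xdrop)
  anchors <- select_anchors(anchors, threshold = cfg$anchor_threshold)
  empty <- data.frame(contig_id = character(0), query_id = character(0),
                      path = character(0), sequence = character(0),
                      score = integer(0), evalue = numeric(0),
                      q_lo = integer(0), q_hi = integer(0),
                      s_lo = integer(0), s_hi = integer(0),
                      edit = character(0), nmatch = integer(0),
                      nmismatch = integer(0), align_cols = integer(0))
  if (nrow(anchors) == 0L) return(empty)
  qlen <- nchar(query)
  cands <- generate_candidate_paths(ug, anchors, qlen, slack = cfg$path_slack,
                                    max_paths = cfg$max_paths_per_anchor)
  if (length(cands) == 0L) return(empty)
  rows <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    cp <- cands[[i]]
    # band centered on the source anchor's diagonal in path coordinates
    center <- cp$anchor$q_lo - (cp$anchor_offset + cp$anchor$u_lo)
    aln <- banded_smith_waterman(query, cp$sequence,
                                 band_width = band_width_rule(qlen),
                                 band_center = center,
                                 gap_open = cfg$gap_open,
                                 gap_extend = cfg$gap_extend)
    ev <- evalue_of(aln$score, qlen, index$db_residues,
                    lambda = cfg$lambda, K = cfg$K)
    rows[[i]] <- data.frame(
      contig_id = NA_character_, query_id = query_id,
      path = paste(cp$unitigs, collapse = ","), sequence = cp$sequence,
      score = aln$score, evalue = ev,
      q_lo = aln$q_lo, q_hi = aln$q_hi, s_lo = aln$s_lo, s_hi = aln$s_hi,
      edit = aln$edit, nmatch = aln$nmatch, nmismatch = aln$nmismatch,
      align_cols = aln$align_cols)
  }
  out <- do.call(rbind, rows)
  out <- out[out$evalue <= cfg$evalue_cutoff, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  # identical spelled sequences (reachable via different claims) keep best E
  out <- out[order(out$evalue, -out$score, out$path), , drop = FALSE]
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  out$contig_id <- sprintf("%s_contig%03d", query_id, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
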