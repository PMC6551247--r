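# Run configuration and the end-to-end pipeline.

#' GRASP2 run configuration
#'
#' All tunables with validated defaults. Seed length `k` and minimum overlap
#' `l` default to the method's published values (6 and 10); the remaining
#' defaults are this implementation's documented choices.
#'
#' @param l minimum overlap length (default 10).
#' @param k seed length (default 6).
#' @param block_size reads per BWT block (default 100000).
#' @param bubble_depth bubble/tip extension depth, edges (default 10).
#' @param anchor_threshold minimum ungapped anchor score, BLOSUM62 units
#'   (default 25).
#' @param xdrop ungapped extension drop-off (default 20).
#' @param gap_open,gap_extend affine gap penalties (11 / 1).
#' @param lambda,K gapped Karlin-Altschul parameters (0.267 / 0.041).
#' @param evalue_cutoff contig acceptance cutoff (default 1e-3).
#' @param min_identity,min_span read-recruitment thresholds (0.9 / 0.8).
#' @param min_hit_overlap minimum fraction of a read overlapping the contig's
#'   homologous interval to be recruited (default 0.6).
#' @param path_slack candidate-path length tolerance (default 0.2).
#' @param max_paths_per_anchor DFS cap (default 64).
#' @param transitive_reduction apply transitive reduction (default TRUE).
#' @param reduced_alphabet seed in the 10-letter reduced alphabet
#'   (default FALSE).
#' @param rng_seed integer seed recorded for provenance (default 1).
#' @return validated named list of class `grasp_config`.
#' @export
grasp_config <- function(l = 10L, k = 6L, block_size = 100000L,
                         bubble_depth = 10L, anchor_threshold = 25L,
                         xdrop = 20L, gap_open = 11L, gap_extend = 1L,
                         lambda = 0.267, K = 0.041, evalue_cutoff = 1e-3,
                         min_identity = 0.9, min_span = 0.8,
                         min_hit_overlap = 0.6, path_slack = 0.2, max_paths_per_anchor = 64L,
                         transitive_reduction = TRUE,
                         reduced_alphabet = FALSE, rng_seed = 1L) {
  cfg <- list(l = as.integer(l), k = as.integer(k),
              block_size = as.integer(block_size),
              bubble_depth = as.integer(bubble_depth),
              anchor_threshold = as.integer(anchor_threshold),
              xdrop = as.integer(xdrop), gap_open = as.integer(gap_open),
              gap_extend = as.integer(gap_extend),
              lambda = as.numeric(lambda), K = as.numeric(K),
              evalue_cutoff = as.numeric(evalue_cutoff),
              min_identity = as.numeric(min_identity),
              min_span = as.numeric(min_span),
              min_hit_overlap = as.numeric(min_hit_overlap),
              path_slack = as.numeric(path_slack),
              max_paths_per_anchor = as.integer(max_paths_per_anchor),
              transitive_reduction = isTRUE(as.logical(transitive_reduction)),
              reduced_alphabet = isTRUE(as.logical(reduced_alphabet)),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$l >= 1L, cfg$k >= 1L, cfg$block_size >= 1L,
            cfg$bubble_depth >= 1L, cfg$xdrop >= 0L, cfg$gap_open >= 0L,
            cfg$gap_extend >= 0L, cfg$lambda > 0, cfg$K > 0,
            cfg$evalue_cutoff > 0, cfg$min_identity >= 0,
            cfg$min_identity <= 1, cfg$min_span >= 0, cfg$min_span <= 1,
            cfg$min_hit_overlap >= 0, cfg$min_hit_overlap <= 1,
            cfg$path_slack >= 0, cfg$max_paths_per_anchor >= 1L)
  class(cfg) <- "grasp_config"
  cfg
}

#' Run the full pipeline: build, assemble, recruit
#'
#' Builds the index from `reads_fasta`, assembles homologous contigs for every
#' query in `query_fasta`, recruits the reads onto the contigs, and writes the
#' output bundle (index directory, contigs FASTA, 12-column hit table,
#' recruitment TSV, config snapshot) under `out_dir`.
#'
#' @param reads_fasta FASTA of peptide reads (the database).
#' @param query_fasta FASTA of reference proteins.
#' @param out_dir output directory.
#' @param config a [grasp_config()].
#' @return invisibly, a list: `index`, `contigs`, `recruited`, `counts`.
#' @export
run_pipeline <- function(reads_fasta, query_fasta, out_dir,
                         config = grasp_config()) {
  db <- read_fasta(reads_fasta)
  qs <- read_fasta(query_fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  message(sprintf("[build] %d reads", length(db$seqs)))
  index <- grasp_index(db$seqs, db$ids, config = config)
  save_index(index, file.path(out_dir, "index"))

  message(sprintf("[assemble] %d unitigs, %d queries",
                  nrow(index$unitigs$unitigs), length(qs$seqs)))
  contigs <- do.call(rbind, lapply(seq_along(qs$seqs), function(i) {
    assemble_homologs(qs$seqs[i], index, query_id = qs$ids[i])
  }))
  if (is.null(contigs)) {
    contigs <- assemble_homologs(paste(rep("A", config$k), collapse = ""),
                                 index)[0, ]
  }
  if (nrow(contigs) > 0L) {
    headers <- sprintf("%s path=%s score=%d evalue=%.3g", contigs$contig_id,
                       contigs$path, contigs$score, contigs$evalue)
    write_fasta(headers, contigs$sequence,
                file.path(out_dir, "contigs.faa"))
  } else {
    write_fasta(character(0) , character(0),
                file.path(out_dir, "contigs.faa"))
  }
  write_hits_table(contigs, file.path(out_dir, "hits.tsv"))

  message(sprintf("[map] %d contigs", nrow(contigs)))
  recruited <- recruit(contigs, db$seqs, db$ids,
                       min_identity = config$min_identity,
                       min_span = config$min_span,
                       min_hit_overlap = config$min_hit_overlap,
                       k = config$k,
                       gap_open = config$gap_open,
                       gap_extend = config$gap_extend)
  write_tsv_atomic(recruited, file.path(out_dir, "reads.tsv"))
  atomic_write(file.path(out_dir, "run_config.json"), function(tmp) {
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  })
  counts <- list(reads = length(db$seqs), overlaps = nrow(index$overlaps),
                 unitigs = nrow(index$unitigs$unitigs),
                 contigs = nrow(contigs), recruited = nrow(recruited))
  message(sprintf("[done] %d reads recruited", counts$recruited))
  invisible(list(index = index, contigs = contigs, recruited = recruited,
                 counts = counts))
}
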