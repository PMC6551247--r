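# File formats: FASTA in/out (via Biostrings), GFA-like unitig export,
# on-disk index persistence, tabular outputs. All artifact writes are atomic
# (write to a temporary file in the target directory, then rename).

INDEX_FORMAT_VERSION <- 1L

#' Read a protein FASTA file
#' @param path FASTA file.
#' @return list with `ids` (first token of each header) and `seqs`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) stop("no sequences in ", path)
  list(ids = sub("\\s.*$", "", names(x)), seqs = as.character(unname(x)))
}

#' Write a protein FASTA file (atomically)
#' @param ids,seqs sequence names and strings.
#' @param path output file.
#' @export
write_fasta <- function(ids, seqs, path) {
  x <- Biostrings::AAStringSet(setNames(seqs, ids))
  atomic_write(path, function(tmp) Biostrings::writeXStringSet(x, tmp))
}

#' @keywords internal
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  ok <- TRUE
  invisible(path)
}

#' @keywords internal
write_tsv_atomic <- function(df, path) {
  atomic_write(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Export the unitig graph as GFA-like text
#'
#' Segments (`S` lines) carry unitig sequences; links (`L` lines) carry the
#' junction overlap as a CIGAR-like `<n>M`.
#'
#' @param ug a `unitig_graph`.
#' @param path output file.
#' @export
write_gfa <- function(ug, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines("H\tVN:Z:1.0", con)
    writeLines(sprintf("S\t%d\t%s", ug$unitigs$unitig_id,
                       ug$unitigs$sequence), con)
    if (nrow(ug$links) > 0L) {
      writeLines(sprintf("L\t%d\t+\t%d\t+\t%dM", ug$links$from, ug$links$to,
                         ug$links$overlap), con)
    }
  })
}

#' Save a GRASP2 index to a directory
#'
#' Versioned layout: `manifest.json`, `config.json`, `reads.faa`, per-block
#' BWT/suffix-array files, `unitigs.gfa` and `placements.tsv`. Rank tables are
#' recomputed on load, so a reloaded index equals a rebuilt one field by
#' field.
#'
#' @param index a `grasp2_index`.
#' @param dir output directory (created if missing).
#' @export
save_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(index$ids, index$reads, file.path(dir, "reads.faa"))
  for (blk in index$blocks) {
    df <- data.frame(bwt = blk$bwt, sa_read = blk$sa_read,
                     sa_off = blk$sa_off)
    write_tsv_atomic(df, file.path(dir, sprintf("block%04d.tsv",
                                                blk$block_id)))
  }
  write_tsv_atomic(index$overlaps, file.path(dir, "overlaps.tsv"))
  write_tsv_atomic(index$containments, file.path(dir, "containments.tsv"))
  write_gfa(index$unitigs, file.path(dir, "unitigs.gfa"))
  write_tsv_atomic(index$unitigs$members, file.path(dir, "placements.tsv"))
  atomic_write(file.path(dir, "config.json"), function(tmp) {
    jsonlite::write_json(unclass(index$config), tmp, auto_unbox = TRUE,
                         digits = NA)
  })
  atomic_write(file.path(dir, "manifest.json"), function(tmp) {
    jsonlite::write_json(list(
      format_version = INDEX_FORMAT_VERSION,
      n_reads = length(index$reads),
      n_blocks = length(index$blocks),
      db_residues = index$db_residues
    ), tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(dir)
}

#' Load a GRASP2 index from a directory
#'
#' @param dir directory produced by [save_index()].
#' @return a `grasp2_index` (the string graph is re-derived from the stored
#'   overlaps/containments; rank tables are recomputed from the stored BWTs).
#' @export
load_index <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("not an index directory: ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(as.integer(mf$format_version), INDEX_FORMAT_VERSION)) {
    stop("incompatible index version: ", mf$format_version)
  }
  cfg <- do.call(grasp_config,
                 jsonlite::read_json(file.path(dir, "config.json"),
                                     simplifyVector = TRUE))
  fa <- read_fasta(file.path(dir, "reads.faa"))
  reads <- fa$seqs
  block_of <- ceiling(seq_along(reads) / cfg$block_size)
  idx_by_block <- split(seq_along(reads), block_of)
  blocks <- lapply(seq_len(mf$n_blocks), function(b) {
    df <- utils::read.table(file.path(dir, sprintf("block%04d.tsv", b)),
                            header = TRUE, sep = "\t")
    ridx <- idx_by_block[[b]]
    seqs <- reads[ridx]
    bwt <- as.integer(df$bwt)
    nsym <- length(BWT_ALPHABET)
    counts <- tabulate(bwt + 1L, nbins = nsym)
    occ <- matrix(0L, nrow = length(bwt) + 1L, ncol = nsym)
    for (k in which(counts > 0L)) occ[, k] <- c(0L, cumsum(bwt == (k - 1L)))
    structure(list(
      block_id = b, read_index = as.integer(ridx), lens = nchar(seqs),
      n_reads = length(ridx), bwt = bwt,
      c_array = cumsum(c(0L, counts))[seq_len(nsym)], occ = occ,
      sa_read = as.integer(df$sa_read), sa_off = as.integer(df$sa_off),
      sent_rows = which(bwt == 0L)
    ), class = "bwt_block")
  })
  overlaps <- utils::read.table(file.path(dir, "overlaps.tsv"),
                                header = TRUE, sep = "\t")
  containments <- utils::read.table(file.path(dir, "containments.tsv"),
                                    header = TRUE, sep = "\t")
  sg <- build_graph(overlaps, containments, reads)
  sg <- clean_graph(sg, depth = cfg$bubble_depth,
                    transitive = cfg$transitive_reduction)
  ug <- collapse_unitigs(sg)
  sidx <- index_seeds(ug, k = cfg$k, reduced = cfg$reduced_alphabet)
  structure(list(reads = reads, ids = fa$ids, blocks = blocks,
                 overlaps = overlaps, containments = containments,
                 graph = sg, unitigs = ug, seed_index = sidx,
                 db_residues = sum(nchar(reads)), config = cfg),
            class = "grasp2_index")
}

#' Write contigs in a 12-column tabular layout
#'
#' The columns follow the familiar hit-table dialect: query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end, subject
#' start/end (1-based inclusive), E-value, bit-like score.
#'
#' @param contigs contig data.frame from [assemble_homologs()].
#' @param path output file.
#' @export
write_hits_table <- function(contigs, path) {
  if (nrow(contigs) > 0L) {
    gaps <- vapply(contigs$edit, function(e) {
      pe <- parse_edit(e)
      sum(pe$op %in% c("I", "D"))
    }, numeric(1))
    df <- data.frame(
      query = contigs$query_id, subject = contigs$contig_id,
      pident = round(100 * contigs$nmatch / contigs$align_cols, 2),
      length = contigs$align_cols, mismatch = contigs$nmismatch,
      gapopen = gaps, qstart = contigs$q_lo + 1L, qend = contigs$q_hi,
      sstart = contigs$s_lo + 1L, send = contigs$s_hi,
      evalue = signif(contigs$evalue, 3), score = contigs$score)
  } else {
    df <- data.frame(query = character(0), subject = character(0),
                     pident = numeric(0), length = integer(0),
                     mismatch = integer(0), gapopen = integer(0),
                     qstart = integer(0), qend = integer(0),
                     sstart = integer(0), send = integer(0),
                     evalue = numeric(0), score = integer(0))
  }
  atomic_write(path, function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  })
}
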