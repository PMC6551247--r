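# Synthetic peptide communities with planted homologs and ground-truth
# labels. Works directly in amino-acid space: random background proteomes,
# homolog copies planted by BLOSUM62-biased substitution to a target identity,
# and fixed-length error-bearing reads with recorded origins. Defaults mirror
# a 10X / 100 bp / 1%-error nucleotide protocol at the peptide level
# (read length 33 aa ~ 100 bp / 3).

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

.random_peptide <- function(n, freq = AA_BACKGROUND_FREQ) {
  paste(sample(names(freq), n, replace = TRUE, prob = freq), collapse = "")
}

# BLOSUM62-biased substitution: replacement residue drawn with probability
# proportional to 2^(score/2) among the 19 alternatives.
.mutate_residues <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  m <- blosum62_matrix()
  res20 <- setdiff(rownames(m), "X")
  for (p in positions) {
    alt <- setdiff(res20, chars[p])
    w <- 2^(m[chars[p], alt] / 2)
    chars[p] <- sample(alt, 1L, prob = w)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic peptide community with planted homologs
#'
#' Background proteomes are random residue strings; for each query, homolog
#' copies are planted into chosen genomes by substituting residues
#' (BLOSUM62-biased) down to the target identity. Planted intervals never
#' overlap within a genome. Fully reproducible from `seed`.
#'
#' @param n_genomes number of genomes (default 5).
#' @param genome_length proteome length per genome, residues (default 600).
#' @param n_queries number of reference proteins (default 2).
#' @param homolog_identity target identity of planted copies, in (0.4, 1]
#'   (default 0.75, the divergence regime of a ~77%-similar community).
#' @param seed integer RNG seed.
#' @param query_length reference protein length (default 150).
#' @param copies_per_query planted copies per query (default 1), placed in
#'   round-robin genomes.
#' @param freq background residue frequencies (default SwissProt-like).
#' @return a `synthetic_community`: `proteomes`, `genome_ids`, `queries`,
#'   `query_ids`, `planted` (query_id, genome, start, end [0-based half-open],
#'   identity_target, identity_realized), `seed`.
#' @export
generate_community <- function(n_genomes = 5L, genome_length = 600L,
                               n_queries = 2L, homolog_identity = 0.75,
                               seed = 1L, query_length = 150L,
                               copies_per_query = 1L,
                               freq = AA_BACKGROUND_FREQ) {
  stopifnot(n_genomes >= 1L, genome_length >= 1L, n_queries >= 1L,
            query_length >= 1L, copies_per_query >= 1L)
  if (homolog_identity <= 0.4 || homolog_identity > 1) {
    stop("homolog_identity must lie in (0.4, 1]")
  }
  if (query_length > genome_length) {
    stop("query_length must not exceed genome_length")
  }
  n_sub <- round((1 - homolog_identity) * query_length)
  if (homolog_identity < 1 && n_sub == 0L) {
    stop("infeasible identity: rounds to zero substitutions")
  }
  .with_seed(seed, {
    proteomes <- vapply(seq_len(n_genomes), function(g) {
      .random_peptide(genome_length, freq)
    }, character(1))
    genome_ids <- sprintf("genome%02d", seq_len(n_genomes))
    queries <- vapply(seq_len(n_queries), function(q) {
      .random_peptide(query_length, freq)
    }, character(1))
    query_ids <- sprintf("query%02d", seq_len(n_queries))

    planted <- list()
    taken <- vector("list", n_genomes)  # occupied intervals per genome
    g_next <- 0L
    for (q in seq_len(n_queries)) {
      for (cp in seq_len(copies_per_query)) {
        g <- (g_next %% n_genomes) + 1L
        g_next <- g_next + 1L
        # find a start that does not overlap existing planted intervals
        start <- NA_integer_
        for (try in seq_len(200L)) {
          s <- sample.int(genome_length - query_length + 1L, 1L) - 1L
          iv <- taken[[g]]
          clash <- !is.null(iv) &&
            any(s < iv[, 2L] & (s + query_length) > iv[, 1L])
          if (!clash) { start <- s; break }
        }
        if (is.na(start)) stop("could not place homolog: genome too crowded")
        taken[[g]] <- rbind(taken[[g]], c(start, start + query_length))
        hom <- queries[q]
        if (n_sub > 0L) {
          pos <- sample.int(query_length, n_sub)
          hom <- .mutate_residues(hom, pos)
        }
        substr(proteomes[g], start + 1L, start + query_length) <- hom
        realized <- mean(strsplit(hom, "")[[1]] ==
                           strsplit(queries[q], "")[[1]])
        planted[[length(planted) + 1L]] <- data.frame(
          query_id = query_ids[q], genome = genome_ids[g],
          start = start, end = start + query_length,
          identity_target = homolog_identity, identity_realized = realized)
      }
    }
    structure(list(proteomes = proteomes, genome_ids = genome_ids,
                   queries = queries, query_ids = query_ids,
                   planted = do.call(rbind, planted), seed = seed),
              class = "synthetic_community")
  })
}

#' Shred a community into error-bearing peptide reads with truth labels
#'
#' Uniform random start positions at expected depth `coverage`; independent
#' per-residue substitution errors at `error_rate`. Reads fully inside a
#' planted homolog interval are labeled `homolog` (with the query id), reads
#' not touching any interval `non_homolog`, and reads straddling an interval
#' endpoint `boundary` (excluded from evaluation counts downstream).
#'
#' @param community a `synthetic_community`.
#' @param read_length residues per read (default 33).
#' @param coverage expected per-residue depth (default 10).
#' @param error_rate per-residue substitution probability (default 0.01).
#' @param seed integer RNG seed.
#' @return list: `reads`, `ids`, `truth` (data.frame read_id, genome, start,
#'   end, label, query_id).
#' @export
shred_reads <- function(community, read_length = 33L, coverage = 10,
                        error_rate = 0.01, seed = 1L) {
  stopifnot(inherits(community, "synthetic_community"), coverage > 0)
  lens <- nchar(community$proteomes)
  if (read_length > min(lens)) stop("read_length exceeds a genome length")
  .with_seed(seed, {
    reads <- character(0); genome <- character(0)
    rstart <- integer(0)
    for (g in seq_along(community$proteomes)) {
      L <- lens[g]
      n <- round(coverage * L / read_length)
      starts <- sample.int(L - read_length + 1L, n, replace = TRUE) - 1L
      seqs <- substring(community$proteomes[g], starts + 1L,
                        starts + read_length)
      if (error_rate > 0) {
        n_err <- stats::rbinom(n, read_length, error_rate)
        for (r in which(n_err > 0L)) {
          ch <- strsplit(seqs[r], "")[[1]]
          pos <- sample.int(read_length, n_err[r])
          for (p in pos) {
            ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
          }
          seqs[r] <- paste(ch, collapse = "")
        }
      }
      reads <- c(reads, seqs)
      genome <- c(genome, rep(community$genome_ids[g], n))
      rstart <- c(rstart, starts)
    }
    ids <- sprintf("r%06d", seq_along(reads))
    truth <- label_reads(community,
                         data.frame(read_id = ids, genome = genome,
                                    start = rstart,
                                    end = rstart + read_length))
    list(reads = reads, ids = ids, truth = truth)
  })
}

#' Label read origins against planted homolog intervals
#'
#' @param community a `synthetic_community`.
#' @param origins data.frame: read_id, genome, start, end (0-based half-open).
#' @return the same data.frame with `label` (homolog / non_homolog / boundary)
#'   and `query_id` (NA unless homolog).
#' @export
label_reads <- function(community, origins) {
  pl <- community$planted
  label <- rep("non_homolog", nrow(origins))
  query_id <- rep(NA_character_, nrow(origins))
  for (i in seq_len(nrow(origins))) {
    iv <- pl[pl$genome == origins$genome[i], , drop = FALSE]
    if (nrow(iv) == 0L) next
    s <- origins$start[i]; e <- origins$end[i]
    inside <- which(s >= iv$start & e <= iv$end)
    touch <- which(s < iv$end & e > iv$start)
    if (length(inside) > 0L) {
      label[i] <- "homolog"
      query_id[i] <- iv$query_id[inside[1L]]
    } else if (length(touch) > 0L) {
      label[i] <- "boundary"
    }
  }
  origins$label <- label
  origins$query_id <- query_id
  origins
}
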