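# Independent brute-force oracles and fixture generators. Everything here is
# deliberately naive (direct scans, exhaustive enumeration, full-matrix DP via
# Biostrings) and never calls into the code paths it checks.

AA20_T <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_peptides <- function(n, min_len = 12L, max_len = 30L) {
  vapply(seq_len(n), function(i) {
    L <- if (min_len == max_len) min_len else sample(min_len:max_len, 1L)
    paste(sample(AA20_T, L, replace = TRUE), collapse = "")
  }, character(1))
}

# reads shredded from one random genome: guaranteed overlap structure
shredded_reads <- function(genome_len = 250L, coverage = 12, read_len = 30L,
                           genome = NULL) {
  if (is.null(genome)) {
    genome <- paste(sample(AA20_T, genome_len, replace = TRUE), collapse = "")
  }
  n <- round(coverage * nchar(genome) / read_len)
  starts <- sample.int(nchar(genome) - read_len + 1L, n, replace = TRUE)
  substring(genome, starts, starts + read_len - 1L)
}

# all (possibly overlapping) occurrence start offsets (0-based) of pattern
naive_occurrences <- function(reads, pattern) {
  k <- nchar(pattern)
  out <- lapply(seq_along(reads), function(i) {
    L <- nchar(reads[i])
    if (L < k) return(NULL)
    pos <- which(substring(reads[i], seq_len(L - k + 1L),
                           seq_len(L - k + 1L) + k - 1L) == pattern)
    if (length(pos) == 0L) return(NULL)
    data.frame(read = i, offset = pos - 1L)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(read = integer(0), offset = integer(0)) else out
}

# maximal proper suffix-prefix overlaps, all ordered pairs, O(n^2 L)
naive_overlaps <- function(reads, l) {
  src <- integer(0); tgt <- integer(0); len <- integer(0)
  for (i in seq_along(reads)) {
    for (j in seq_along(reads)) {
      if (i == j) next
      top <- min(nchar(reads[i]), nchar(reads[j])) - 1L
      if (top < l) next
      for (m in top:l) {
        if (substring(reads[i], nchar(reads[i]) - m + 1L) ==
            substring(reads[j], 1L, m)) {
          src <- c(src, i); tgt <- c(tgt, j); len <- c(len, m)
          break
        }
      }
    }
  }
  df <- data.frame(source = src, target = tgt, length = len)
  df[order(df$source, df$target), , drop = FALSE]
}

# reads that are substrings of another read (global, ignoring blocks)
naive_contained <- function(reads) {
  out <- logical(length(reads))
  for (i in seq_along(reads)) {
    for (j in seq_along(reads)) {
      if (i == j) next
      li <- nchar(reads[i]); lj <- nchar(reads[j])
      if (li > lj || (li == lj && i < j)) next
      if (grepl(reads[i], reads[j], fixed = TRUE)) { out[i] <- TRUE; break }
    }
  }
  which(out)
}

# maximal unbranched paths of a directed edge list, enumerated directly
naive_unipaths <- function(nodes, edges) {
  outdeg <- vapply(nodes, function(v) sum(edges$source == v), integer(1))
  indeg <- vapply(nodes, function(v) sum(edges$target == v), integer(1))
  names(outdeg) <- names(indeg) <- nodes
  succ <- function(v) edges$target[edges$source == v]
  is_internal_edge <- function(u, v) {
    outdeg[as.character(u)] == 1L && indeg[as.character(v)] == 1L
  }
  starts <- nodes[vapply(nodes, function(v) {
    if (indeg[as.character(v)] != 1L) return(TRUE)
    !is_internal_edge(edges$source[edges$target == v], v)
  }, logical(1))]
  paths <- list()
  used <- integer(0)
  for (v in starts) {
    p <- v
    while (outdeg[as.character(p[length(p)])] == 1L) {
      nx <- succ(p[length(p)])
      if (indeg[as.character(nx)] != 1L || nx %in% p) break
      p <- c(p, nx)
    }
    paths[[length(paths) + 1L]] <- p
    used <- c(used, p)
  }
  for (v in setdiff(nodes, used)) {   # pure cycles
    if (v %in% used) next
    p <- v
    repeat {
      nx <- succ(p[length(p)])
      if (length(nx) != 1L || nx %in% p) break
      p <- c(p, nx)
    }
    paths[[length(paths) + 1L]] <- p
    used <- c(used, p)
  }
  paths
}

# independent full-matrix local alignment score (Biostrings DP)
.B62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})
biostrings_sw <- function(a, b, gap_open = 11, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = .B62, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
}

# plain R full-matrix affine local DP, independent of the C++ kernel
r_sw_score <- function(a, b, gap_open = 11L, gap_extend = 1L) {
  mat <- blosum62_matrix()
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  m <- length(ac); n <- length(bc)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1); E <- matrix(NEG, m + 1, n + 1)
  F_ <- matrix(NEG, m + 1, n + 1)
  go <- gap_open + gap_extend
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - gap_extend)
      F_[i, j] <- max(H[i - 1, j] - go, F_[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[ac[i - 1], bc[j - 1]],
                     E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# replay an edit string over aligned intervals; TRUE iff consistent
edit_consistent <- function(aln, query, subject) {
  pe <- parse_edit(aln$edit)
  qi <- aln$q_lo; si <- aln$s_lo
  for (r in seq_len(nrow(pe))) {
    for (step in seq_len(pe$len[r])) {
      op <- pe$op[r]
      if (op %in% c("M", "X")) {
        qc <- substring(query, qi + 1L, qi + 1L)
        sc <- substring(subject, si + 1L, si + 1L)
        if (op == "M" && qc != sc) return(FALSE)
        if (op == "X" && qc == sc) return(FALSE)
        qi <- qi + 1L; si <- si + 1L
      } else if (op == "I") {
        si <- si + 1L
      } else if (op == "D") {
        qi <- qi + 1L
      } else return(FALSE)
    }
  }
  qi == aln$q_hi && si == aln$s_hi
}

# per-position BLOSUM62 scores of two equal-length strings (via the
# Biostrings copy of the matrix, independent of the package's lookup)
pair_scores_t <- function(a, b) {
  .B62[cbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]])]
}

# hamming identity of equal-length strings
str_identity <- function(a, b) {
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

unitig_spellings <- function(reads, blocks = 1L, l = 10L, depth = 10L) {
  bl <- build_blocks(reads, block_size = ceiling(length(reads) / blocks))
  ov <- find_overlaps(bl, reads, l = l)
  sg <- build_graph(ov$overlaps, ov$containments, reads)
  sg <- clean_graph(sg, depth = depth)
  sort(collapse_unitigs(sg)$unitigs$sequence)
}

rand_pep1 <- function(L) paste(sample(AA20_T, L, replace = TRUE),
                               collapse = "")

# A 14-unitig condensed graph with the topology of the worked example:
# 3 -> 6 -> 9 -> 12 -> 14, plus 4 -> 12 and 7 -> 12; remaining unitigs are
# isolated. All junction overlaps are 5 residues.
make_worked_graph <- function() {
  set.seed(23)
  J12 <- rand_pep1(5L)
  u <- character(14)
  u[3] <- rand_pep1(40L)
  u[6] <- paste0(substring(u[3], 36L), rand_pep1(35L))
  u[12] <- paste0(J12, rand_pep1(35L))
  u[9] <- paste0(substring(u[6], 36L), rand_pep1(30L), J12)
  u[4] <- paste0(rand_pep1(35L), J12)
  u[7] <- paste0(rand_pep1(35L), J12)
  u[14] <- paste0(substring(u[12], 36L), rand_pep1(35L))
  for (i in c(1, 2, 5, 8, 10, 11, 13)) u[i] <- rand_pep1(40L)
  links <- data.frame(from = c(3L, 6L, 9L, 4L, 7L, 12L),
                      to = c(6L, 9L, 12L, 12L, 12L, 14L),
                      overlap = 5L)
  structure(list(
    unitigs = data.frame(unitig_id = 1:14, sequence = u, length = nchar(u),
                         n_members = 1L),
    members = data.frame(unitig_id = integer(0), read = integer(0),
                         offset = integer(0)),
    links = links), class = "unitig_graph")
}

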