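# Seeding and ungapped anchor extension against the unitig database.

#' Index every k-mer of the unitig set
#'
#' Maps each length-k window (windows containing 'X' are skipped) of every
#' unitig to its positions. With `reduced = TRUE` both index and later lookups
#' use a 10-letter reduced alphabet for seeding only; scoring always uses the
#' full alphabet.
#'
#' @param unitigs a `unitig_graph` or character vector of unitig sequences.
#' @param k seed length (default 6).
#' @param reduced use the reduced seeding alphabet (default FALSE).
#' @return a `seed_index` (environment-backed hash: k-mer -> matrix of
#'   (unitig, pos)); positions are 0-based.
#' @export
index_seeds <- function(unitigs, k = 6L, reduced = FALSE) {
  seqs <- if (inherits(unitigs, "unitig_graph")) unitigs$unitigs$sequence
          else unitigs
  if (k < 1L) stop("k must be >= 1")
  h <- new.env(parent = emptyenv(), size = 4096L)
  for (u in seq_along(seqs)) {
    s <- seqs[u]
    L <- nchar(s)
    if (L < k) next
    key_src <- if (reduced) reduce_alphabet(s) else s
    kmers <- substring(key_src, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    raw <- substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    ok <- !grepl("X", raw, fixed = TRUE)
    for (p in which(ok)) {
      key <- kmers[p]
      h[[key]] <- rbind(h[[key]], c(u, p - 1L))
    }
  }
  structure(list(hash = h, k = k, reduced = reduced, n_unitigs = length(seqs)),
            class = "seed_index")
}

#' Seed matches between a query and the indexed unitigs
#'
#' @param index a `seed_index`.
#' @param query peptide string.
#' @return data.frame: query_pos, unitig_id, unitig_pos (0-based), k.
#' @export
seed_matches <- function(index, query) {
  k <- index$k
  L <- nchar(query)
  empty <- data.frame(query_pos = integer(0), unitig_id = integer(0),
                      unitig_pos = integer(0), k = integer(0))
  if (L < k) return(empty)
  raw <- substring(query, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  keys <- if (index$reduced) vapply(raw, reduce_alphabet, character(1)) else raw
  res <- list()
  for (p in seq_along(keys)) {
    if (grepl("X", raw[p], fixed = TRUE)) next
    m <- index$hash[[keys[p]]]
    if (is.null(m)) next
    res[[length(res) + 1L]] <- data.frame(query_pos = p - 1L,
                                          unitig_id = m[, 1L],
                                          unitig_pos = m[, 2L], k = k)
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Ungapped seed extension (X-drop)
#'
#' Extends a seed match along its diagonal in both directions and returns the
#' best-scoring ungapped segment containing the seed. The scan in each
#' direction stops once the running score falls more than `xdrop` below the
#' running best, which bounds work without affecting the result unless the
#' optimum lies beyond a deeper trough.
#'
#' @param query,unitig peptide strings.
#' @param query_pos,unitig_pos 0-based seed start positions.
#' @param k seed length.
#' @param xdrop drop-off threshold in score units (default 20).
#' @param mat substitution matrix in code order.
#' @return list: `score`, `q_lo`, `q_hi`, `u_lo`, `u_hi` (0-based half-open),
#'   `diagonal` (query_pos - unitig_pos).
#' @export
ungapped_extend <- function(query, unitig, query_pos, unitig_pos, k,
                            xdrop = 20L, mat = blosum62_matrix()) {
  qc <- encode_peptide(query)
  uc <- encode_peptide(unitig)
  qp <- query_pos + 1L  # 1-based seed start
  up <- unitig_pos + 1L
  stopifnot(qp + k - 1L <= length(qc), up + k - 1L <= length(uc))
  sc <- function(i, j) mat[qc[i], uc[j]]
  seed_score <- sum(mat[cbind(qc[qp:(qp + k - 1L)], uc[up:(up + k - 1L)])])
  # rightward
  best_r <- 0L; ext_r <- 0L; run <- 0L
  i <- qp + k; j <- up + k
  while (i <= length(qc) && j <= length(uc)) {
    run <- run + sc(i, j)
    if (run > best_r) { best_r <- run; ext_r <- i - (qp + k) + 1L }
    if (best_r - run > xdrop) break
    i <- i + 1L; j <- j + 1L
  }
  # leftward
  best_l <- 0L; ext_l <- 0L; run <- 0L
  i <- qp - 1L; j <- up - 1L
  while (i >= 1L && j >= 1L) {
    run <- run + sc(i, j)
    if (run > best_l) { best_l <- run; ext_l <- qp - i }
    if (best_l - run > xdrop) break
    i <- i - 1L; j <- j - 1L
  }
  list(score = seed_score + best_l + best_r,
       q_lo = query_pos - ext_l, q_hi = query_pos + k + ext_r,
       u_lo = unitig_pos - ext_l, u_hi = unitig_pos + k + ext_r,
       diagonal = query_pos - unitig_pos)
}

#' Compute anchors for a query against a unitig set
#'
#' Runs [seed_matches()] then [ungapped_extend()] on every seed.
#'
#' @param index a `seed_index`.
#' @param unitig_seqs unitig sequences (indexed by unitig id).
#' @param query peptide string.
#' @param xdrop X-drop parameter.
#' @return data.frame of anchor candidates (one per seed): unitig_id, score,
#'   q_lo, q_hi, u_lo, u_hi, diagonal, query_pos.
#' @export
compute_anchors <- function(index, unitig_seqs, query, xdrop = 20L) {
  sm <- seed_matches(index, query)
  empty <- data.frame(unitig_id = integer(0), score = integer(0),
                      q_lo = integer(0), q_hi = integer(0),
                      u_lo = integer(0), u_hi = integer(0),
                      diagonal = integer(0), query_pos = integer(0))
  if (nrow(sm) == 0L) return(empty)
  # one extension per distinct (unitig, diagonal, seed) is wasteful when seeds
  # chain on the same diagonal; keep the first seed per (unitig, diagonal)
  sm <- sm[!duplicated(paste(sm$unitig_id, sm$query_pos - sm$unitig_pos)), ,
           drop = FALSE]
  res <- vector("list", nrow(sm))
  for (r in seq_len(nrow(sm))) {
    a <- ungapped_extend(query, unitig_seqs[sm$unitig_id[r]],
                         sm$query_pos[r], sm$unitig_pos[r], sm$k[r],
                         xdrop = xdrop)
    res[[r]] <- data.frame(unitig_id = sm$unitig_id[r], score = a$score,
                           q_lo = a$q_lo, q_hi = a$q_hi,
                           u_lo = a$u_lo, u_hi = a$u_hi,
                           diagonal = a$diagonal, query_pos = sm$query_pos[r])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter, deduplicate and order anchors
#'
#' Keeps anchors scoring at least `threshold`, one per unitig (the best; ties
#' by smaller query position), ordered by descending score with ties broken by
#' (unitig_id, query_pos).
#'
#' @param anchors data.frame from [compute_anchors()].
#' @param threshold minimum ungapped score (default 25).
#' @return ordered, deduplicated anchor data.frame.
#' @export
select_anchors <- function(anchors, threshold = 25L) {
  a <- anchors[anchors$score >= threshold, , drop = FALSE]
  if (nrow(a) == 0L) {
    rownames(a) <- NULL
    return(a)
  }
  a <- a[order(a$unitig_id, -a$score, a$query_pos), , drop = FALSE]
  a <- a[!duplicated(a$unitig_id), , drop = FALSE]
  a <- a[order(-a$score, a$unitig_id, a$query_pos), , drop = FALSE]
  rownames(a) <- NULL
  a
}
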