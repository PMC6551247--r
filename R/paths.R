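# Candidate homologous path generation: anchor-ordered DFS over the condensed
# unitig graph with claiming-based redundancy suppression.

#' Generate candidate homologous paths
#'
#' Anchors are processed in [select_anchors()] order. From each surviving
#' anchor, depth-first search extends toward both the N- and C-terminus until
#' the spelled length on that side reaches the query-proportional target
#' (`query_length * (1 + slack)`, apportioned by the anchor's position on the
#' query); the anchor's unitig is always wholly included. Unitigs claimed by
#' the candidate paths of earlier anchors may not be entered, and anchors on
#' any unitig visited by a DFS are dropped from the pending list. Branch
#' points yield one candidate path per (left walk, right walk) combination, up
#' to `max_paths` per anchor, explored in order of descending ungapped score
#' of the next unitig, ties by unitig id.
#'
#' @param ug a `unitig_graph`.
#' @param anchors ordered anchors from [select_anchors()].
#' @param query_length reference protein length, residues.
#' @param slack spelled-length tolerance (default 0.2).
#' @param max_paths cap on candidate paths per anchor (default 64).
#' @return list of candidate paths; each has `unitigs` (ordered walk),
#'   `sequence`, `anchor` (the seeding anchor row), `anchor_offset` (0-based
#'   offset of the anchor unitig's first residue in `sequence`).
#' @export
generate_candidate_paths <- function(ug, anchors, query_length, slack = 0.2,
                                     max_paths = 64L) {
  if (nrow(anchors) == 0L) return(list())
  ulen <- ug$unitigs$length
  links <- ug$links
  lkey <- paste(links$from, links$to)
  uscore <- rep(0, nrow(ug$unitigs))
  uscore[anchors$unitig_id] <- anchors$score
  nbrs <- function(u, dir) {
    if (dir == "right") {
      idx <- which(links$from == u)
      data.frame(u = links$to[idx], ov = links$overlap[idx])
    } else {
      idx <- which(links$to == u)
      data.frame(u = links$from[idx], ov = links$overlap[idx])
    }
  }
  claimed <- rep(FALSE, nrow(ug$unitigs))
  pending <- rep(TRUE, nrow(anchors))
  paths <- list()

  for (ai in seq_len(nrow(anchors))) {
    if (!pending[ai]) next
    pending[ai] <- FALSE
    a <- anchors[ai, ]
    if (claimed[a$unitig_id]) next
    visited <- a$unitig_id

    # residues still wanted on each side, beyond the anchor's own unitig
    need_left <- ceiling(a$q_lo * (1 + slack)) - a$u_lo
    need_right <- ceiling((query_length - a$q_hi) * (1 + slack)) -
      (ulen[a$unitig_id] - a$u_hi)

    walks_dir <- function(dir, need) {
      acc <- list()
      dfs <- function(walk, got) {
        if (length(acc) >= max_paths) return()
        nb <- nbrs(walk[length(walk)], dir)
        nb <- nb[!claimed[nb$u] & !(nb$u %in% walk), , drop = FALSE]
        if (got >= need || nrow(nb) == 0L) {
          acc[[length(acc) + 1L]] <<- walk[-1L]  # strip the anchor unitig
          return()
        }
        nb <- nb[order(-uscore[nb$u], nb$u), , drop = FALSE]
        for (r in seq_len(nrow(nb))) {
          visited <<- union(visited, nb$u[r])
          dfs(c(walk, nb$u[r]), got + ulen[nb$u[r]] - nb$ov[r])
        }
      }
      dfs(a$unitig_id, 0L)
      acc
    }
    lefts <- walks_dir("left", need_left)
    rights <- walks_dir("right", need_right)

    new_unitigs <- integer(0)
    count <- 0L
    for (lw in lefts) {
      for (rw in rights) {
        if (count >= max_paths) break
        walk <- c(rev(lw), a$unitig_id, rw)
        seqs <- spell_unitig_walk(ug, walk)
        aoff <- 0L
        if (length(lw) > 0L) {
          left_walk <- c(rev(lw), a$unitig_id)
          aoff <- nchar(spell_unitig_walk(ug, left_walk)) - ulen[a$unitig_id]
        }
        paths[[length(paths) + 1L]] <- list(
          unitigs = walk, sequence = seqs, anchor = a, anchor_offset = aoff)
        new_unitigs <- union(new_unitigs, walk)
        count <- count + 1L
      }
      if (count >= max_paths) break
    }
    claimed[new_unitigs] <- TRUE
    pending[pending & anchors$unitig_id %in% visited] <- FALSE
  }
  # drop exact duplicate walks (possible when left/right combinations repeat)
  keys <- vapply(paths, function(p) paste(p$unitigs, collapse = ","),
                 character(1))
  paths[!duplicated(keys)]
}
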