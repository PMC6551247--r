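# SNP-aware string graph: reads as nodes, maximal proper suffix-prefix
# overlaps as directed edges (N-terminal -> C-terminal). Each edge carries the
# target's non-overlapping suffix, so spelling a path reconstructs every
# member read verbatim. Cleanup deliberately removes only provably redundant
# structure: bubbles whose two spellings are *identical* and tips whose
# spelling is contained in a neighboring through-path -- single-residue
# variants from low-abundance genomes survive.

#' Build a string graph from overlaps and containments
#'
#' Contained reads are excluded from the node set (they are recorded on the
#' returned object for recruitment accounting). Every edge label is checked
#' against the read sequences; a disagreeing overlap is an error.
#'
#' @param overlaps data.frame (source, target, length) from [find_overlaps()].
#' @param containments data.frame (contained, container, offset).
#' @param reads full read set, global indexing.
#' @return a `string_graph`: nodes (read indices), edges
#'   (source, target, length, label), seqs, contained.
#' @export
build_graph <- function(overlaps, containments, reads) {
  contained <- unique(containments$contained)
  nodes <- setdiff(seq_along(reads), contained)
  ed <- overlaps[overlaps$source %in% nodes & overlaps$target %in% nodes &
                   overlaps$source != overlaps$target, , drop = FALSE]
  if (nrow(ed) > 0L) {
    suf <- substring(reads[ed$source],
                     nchar(reads[ed$source]) - ed$length + 1L)
    pre <- substring(reads[ed$target], 1L, ed$length)
    if (any(suf != pre)) {
      bad <- which(suf != pre)[1L]
      stop("inconsistent overlap: reads ", ed$source[bad], " -> ",
           ed$target[bad], " disagree over ", ed$length[bad], " residues")
    }
    ed$label <- substring(reads[ed$target], ed$length + 1L)
    stopifnot(all(nchar(ed$label) > 0L))
  } else {
    ed$label <- character(0)
  }
  rownames(ed) <- NULL
  structure(list(nodes = as.integer(nodes), edges = ed, seqs = reads,
                 contained = containments),
            class = "string_graph")
}

#' @export
print.string_graph <- function(x, ...) {
  cat("string_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges,",
      nrow(x$contained), "contained reads\n")
  invisible(x)
}

# ---- internal graph helpers -------------------------------------------------

# adjacency index: edge rows grouped by source/target for O(1) neighbour
# lookups during path enumeration; rebuilt after every mutation (cheap)
.sg_index <- function(sg) {
  e <- sg$edges
  list(e = e,
       out = split(seq_len(nrow(e)), e$source),
       inn = split(seq_len(nrow(e)), e$target),
       seqs = sg$seqs,
       lens = nchar(sg$seqs))
}

.sg_degrees <- function(sg) {
  out <- table(factor(sg$edges$source, levels = sg$nodes))
  inn <- table(factor(sg$edges$target, levels = sg$nodes))
  list(out = as.integer(out), inn = as.integer(inn))
}

# simple paths leaving v (<= max_edges edges, every prefix emitted), with
# spellings accumulated incrementally; deterministic order (targets ascending)
.paths_out <- function(ix, v, max_edges, max_paths = 400L,
                       forbid = integer(0)) {
  nodes <- list(); spells <- character(0)
  walk <- function(path, spell) {
    if (length(nodes) >= max_paths) return()
    if (length(path) > 1L) {
      nodes[[length(nodes) + 1L]] <<- path
      spells[length(spells) + 1L] <<- spell
    }
    if (length(path) - 1L >= max_edges) return()
    idx <- ix$out[[as.character(path[length(path)])]]
    if (is.null(idx)) return()
    for (k in idx[order(ix$e$target[idx])]) {
      t <- ix$e$target[k]
      if (t %in% path || t %in% forbid) next
      walk(c(path, t), paste0(spell, ix$e$label[k]))
    }
  }
  walk(v, ix$seqs[v])
  list(nodes = nodes, spells = spells)
}

# simple paths entering v, oriented N->C (ending at v); spelling built by
# prepending the new first read's non-overlapping prefix
.paths_in <- function(ix, v, max_edges, max_paths = 400L,
                      forbid = integer(0)) {
  nodes <- list(); spells <- character(0)
  walk <- function(path, spell) {   # path oriented forward, spell matches
    if (length(nodes) >= max_paths) return()
    if (length(path) > 1L) {
      nodes[[length(nodes) + 1L]] <<- path
      spells[length(spells) + 1L] <<- spell
    }
    if (length(path) - 1L >= max_edges) return()
    idx <- ix$inn[[as.character(path[1L])]]
    if (is.null(idx)) return()
    for (k in idx[order(ix$e$source[idx])]) {
      s <- ix$e$source[k]
      if (s %in% path || s %in% forbid) next
      walk(c(s, path),
           paste0(ix$seqs[s], ix$e$label[k],
                  substring(spell, ix$lens[path[1L]] + 1L)))
    }
  }
  walk(v, ix$seqs[v])
  list(nodes = nodes, spells = spells)
}

#' Spell the sequence of a read path
#'
#' @param sg a `string_graph`.
#' @param path integer vector of node (read) indices along existing edges.
#' @return the spelled amino-acid string.
#' @export
spell_path <- function(sg, path) {
  s <- sg$seqs[path[1L]]
  if (length(path) > 1L) {
    key <- paste(sg$edges$source, sg$edges$target)
    idx <- match(paste(path[-length(path)], path[-1L]), key)
    if (anyNA(idx)) stop("path does not follow graph edges")
    s <- paste0(s, paste(sg$edges$label[idx], collapse = ""))
  }
  s
}

.sg_drop_nodes <- function(sg, drop) {
  sg$nodes <- setdiff(sg$nodes, drop)
  sg$edges <- sg$edges[!(sg$edges$source %in% drop |
                           sg$edges$target %in% drop), , drop = FALSE]
  rownames(sg$edges) <- NULL
  sg
}

# ---- transitive reduction ---------------------------------------------------

#' Remove transitive edges (Myers-style)
#'
#' An edge v->w is transitive when some out-neighbour u of v has an edge u->w
#' and the labels compose: label(v->w) == label(v->u) + label(u->w). All
#' transitive edges are marked against the original edge set, then removed in
#' one sweep, so the result is order-independent.
#'
#' @param sg a `string_graph`.
#' @return the reduced graph.
#' @export
reduce_transitive <- function(sg) {
  e <- sg$edges
  if (nrow(e) < 2L) return(sg)
  key <- paste(e$source, e$target)
  drop <- logical(nrow(e))
  by_src <- split(seq_len(nrow(e)), e$source)
  for (idx in by_src) {
    if (length(idx) < 2L) next
    for (j in idx) {                       # candidate transitive edge v->w
      for (i in idx) {
        if (i == j) next
        if (nchar(e$label[i]) >= nchar(e$label[j])) next
        k <- match(paste(e$target[i], e$target[j]), key)
        if (!is.na(k) &&
            e$label[j] == paste0(e$label[i], e$label[k])) {
          drop[j] <- TRUE
          break
        }
      }
    }
  }
  sg$edges <- e[!drop, , drop = FALSE]
  rownames(sg$edges) <- NULL
  sg
}

# ---- bubble removal ---------------------------------------------------------

#' Remove sequence-identical bubbles
#'
#' Two node-disjoint paths between the same node pair whose spelled sequences
#' are identical form a bubble; one branch is deleted. Branch choice: fewer
#' member reads loses; on ties the branch with the larger minimum read index
#' loses. A branch with no intermediate nodes is a direct edge and deleting it
#' is an edge deletion. Paths whose spellings differ in any residue are both
#' retained, preserving polymorphisms.
#'
#' @param sg a `string_graph`.
#' @param depth maximum extension depth in edges from the branching node
#'   (default 10).
#' @return the graph with all identical bubbles removed (a fixed point).
#' @export
remove_bubbles <- function(sg, depth = 10L) {
  stopifnot(depth >= 1L)
  repeat {
    changed <- FALSE
    ix <- .sg_index(sg)
    deg <- .sg_degrees(sg)
    for (v in sg$nodes[deg$out >= 2L]) {
      if (!(v %in% sg$nodes)) next   # removed earlier in this sweep
      repeat {
        act <- .find_bubble_at(ix, v)
        if (is.null(act)) break
        if (act$kind == "nodes") {
          sg <- .sg_drop_nodes(sg, act$drop)
        } else {
          keep <- !(sg$edges$source == act$edge[1L] &
                      sg$edges$target == act$edge[2L])
          sg$edges <- sg$edges[keep, , drop = FALSE]
          rownames(sg$edges) <- NULL
        }
        changed <- TRUE
        ix <- .sg_index(sg)
        if (!(v %in% sg$nodes)) break
      }
    }
    if (!changed) break
  }
  sg
}

.find_bubble_at <- function(ix, v, depth = 10L) {
  pp <- .paths_out(ix, v, max_edges = depth)
  if (length(pp$nodes) < 2L) return(NULL)
  ends <- vapply(pp$nodes, function(p) p[length(p)], integer(1))
  grp <- split(seq_along(pp$nodes), paste(ends, pp$spells))
  for (g in grp) {
    if (length(g) < 2L) next
    for (a in seq_len(length(g) - 1L)) {
      for (b in (a + 1L):length(g)) {
        p1 <- pp$nodes[[g[a]]]; p2 <- pp$nodes[[g[b]]]
        i1 <- p1[-c(1L, length(p1))]; i2 <- p2[-c(1L, length(p2))]
        # rank branches: more intermediates wins; ties keep smaller min id
        win12 <- if (length(i1) != length(i2)) length(i1) > length(i2)
                 else min(c(i1, Inf)) < min(c(i2, Inf))
        loser <- if (win12) list(p = p2, i = i2, other = i1)
                 else list(p = p1, i = i1, other = i2)
        if (length(loser$i) == 0L) {
          return(list(kind = "edge", edge = c(loser$p[1L], loser$p[2L])))
        }
        drop <- setdiff(loser$i, loser$other)
        if (length(drop) > 0L) {
          return(list(kind = "nodes", drop = drop))
        }
      }
    }
  }
  NULL
}

# ---- tip trimming -----------------------------------------------------------

#' Trim redundant tips
#'
#' A tip is a two-node dead-end path (r, t) -- terminating (t has no out-edges
#' and one in-edge) or, symmetrically, beginning. The tip node t is removed
#' only when its spelled two-node sequence is contained in the spelling of
#' some other path through the connecting node r with at least three nodes.
#' Orphan two-node components have no such path and are always retained.
#'
#' @param sg a `string_graph`.
#' @param depth maximum extension depth (edges) when spelling neighbouring
#'   paths (default 10).
#' @return the trimmed graph (a fixed point).
#' @export
trim_tips <- function(sg, depth = 10L) {
  repeat {
    changed <- FALSE
    ix <- .sg_index(sg)
    deg <- .sg_degrees(sg)
    names_deg <- sg$nodes
    for (k in seq_along(names_deg)) {
      t <- names_deg[k]
      if (!(t %in% sg$nodes)) next
      term <- deg$out[k] == 0L && deg$inn[k] == 1L
      beg <- deg$inn[k] == 0L && deg$out[k] == 1L
      if (!term && !beg) next
      e <- ix$e
      if (term) {
        r <- e$source[e$target == t]
        if (length(r) != 1L) next   # degrees shifted earlier in this sweep
        tip_spell <- paste0(ix$seqs[r], e$label[e$source == r & e$target == t])
        alt <- .paths_out(ix, r, depth, max_paths = 200L, forbid = t)
      } else {
        r <- e$target[e$source == t]
        if (length(r) != 1L) next
        tip_spell <- paste0(ix$seqs[t], e$label[e$source == t & e$target == r])
        alt <- .paths_in(ix, r, depth, max_paths = 200L, forbid = t)
      }
      long <- vapply(alt$nodes, length, integer(1)) >= 2L  # r + >=2 = 3 nodes
      if (any(long) &&
          any(grepl(tip_spell, alt$spells[long], fixed = TRUE))) {
        sg <- .sg_drop_nodes(sg, t)
        changed <- TRUE
        ix <- .sg_index(sg)
      }
    }
    if (!changed) break
    # degrees changed; next sweep recomputes
  }
  sg
}

# ---- cleanup driver ---------------------------------------------------------

#' Rectify the string graph
#'
#' Applies transitive reduction, then alternates sequence-identical bubble
#' removal and containment-gated tip trimming to a joint fixed point. This is
#' the step that repairs cross-block containment artifacts left by blockwise
#' overlap detection.
#'
#' @param sg a `string_graph`.
#' @param depth bubble/tip extension depth (default 10).
#' @param transitive apply transitive reduction first (default TRUE).
#' @return the cleaned graph.
#' @export
clean_graph <- function(sg, depth = 10L, transitive = TRUE) {
  if (transitive) sg <- reduce_transitive(sg)
  repeat {
    before <- c(length(sg$nodes), nrow(sg$edges))
    sg <- remove_bubbles(sg, depth)
    sg <- trim_tips(sg, depth)
    if (identical(before, c(length(sg$nodes), nrow(sg$edges)))) break
  }
  sg
}

# ---- unitig collapsing ------------------------------------------------------

#' Collapse unbranched paths into unitigs
#'
#' Maximal unbranched paths (every internal node with in-degree = out-degree
#' = 1) become single unitigs carrying their spelled sequence and the member
#' read placements; remaining edges become links between unitig ends, labeled
#' with the read-overlap length at the junction, so that spelling a unitig
#' walk equals spelling the underlying read path.
#'
#' @param sg a cleaned `string_graph`.
#' @return a `unitig_graph`: `unitigs` (data.frame unitig_id, sequence,
#'   length, n_members), `members` (unitig_id, read, offset), `links`
#'   (from, to, overlap).
#' @export
collapse_unitigs <- function(sg) {
  nodes <- sg$nodes
  e <- sg$edges
  outdeg <- table(factor(e$source, levels = nodes))
  indeg <- table(factor(e$target, levels = nodes))
  names(outdeg) <- names(indeg) <- as.character(nodes)
  out1 <- function(v) e$target[e$source == v]
  # an edge u->v is internal iff outdeg(u) == 1 and indeg(v) == 1
  is_start <- vapply(nodes, function(v) {
    if (indeg[as.character(v)] != 1L) return(TRUE)
    u <- e$source[e$target == v]
    outdeg[as.character(u)] != 1L
  }, logical(1))
  starts <- nodes[is_start]
  chains <- list()
  seen <- integer(0)
  for (v in starts) {
    chain <- v
    cur <- v
    repeat {
      if (outdeg[as.character(cur)] != 1L) break
      nxt <- out1(cur)
      if (indeg[as.character(nxt)] != 1L || nxt %in% chain) break
      chain <- c(chain, nxt)
      cur <- nxt
    }
    chains[[length(chains) + 1L]] <- chain
    seen <- c(seen, chain)
  }
  # isolated cycles (every node internal): break at the smallest node
  left <- setdiff(nodes, seen)
  while (length(left) > 0L) {
    v <- min(left)
    chain <- v
    cur <- v
    repeat {
      nxt <- out1(cur)
      if (length(nxt) != 1L || nxt == v || nxt %in% chain) break
      chain <- c(chain, nxt)
      cur <- nxt
    }
    chains[[length(chains) + 1L]] <- chain
    seen <- c(seen, chain)
    left <- setdiff(left, chain)
  }

  n_uni <- length(chains)
  useq <- character(n_uni)
  members <- vector("list", n_uni)
  node2uni <- integer(0)
  for (u in seq_len(n_uni)) {
    chain <- chains[[u]]
    useq[u] <- spell_path(sg, chain)
    off <- integer(length(chain))
    if (length(chain) > 1L) {
      key <- paste(e$source, e$target)
      ov <- e$length[match(paste(chain[-length(chain)], chain[-1L]), key)]
      off[-1L] <- cumsum(nchar(sg$seqs[chain[-length(chain)]]) - ov)
    }
    members[[u]] <- data.frame(unitig_id = u, read = chain, offset = off)
    node2uni[as.character(chain)] <- u
  }
  members <- do.call(rbind, members)

  first_of <- vapply(chains, function(ch) ch[1L], integer(1))
  last_of <- vapply(chains, function(ch) ch[length(ch)], integer(1))
  internal <- paste(unlist(lapply(chains, function(ch) {
    if (length(ch) > 1L) paste(ch[-length(ch)], ch[-1L]) else character(0)
  })))
  ekey <- paste(e$source, e$target)
  junction <- e[!(ekey %in% internal), , drop = FALSE]
  links <- data.frame(
    from = unname(node2uni[as.character(junction$source)]),
    to = unname(node2uni[as.character(junction$target)]),
    overlap = junction$length
  )
  # sanity: junction edges must leave the last node / enter the first node
  stopifnot(all(junction$source == last_of[links$from]),
            all(junction$target == first_of[links$to]))
  links <- links[order(links$from, links$to), , drop = FALSE]
  rownames(links) <- NULL

  structure(list(
    unitigs = data.frame(unitig_id = seq_len(n_uni), sequence = useq,
                         length = nchar(useq),
                         n_members = vapply(chains, length, integer(1))),
    members = members,
    links = links,
    contained = sg$contained,
    seqs = sg$seqs
  ), class = "unitig_graph")
}

#' @export
print.unitig_graph <- function(x, ...) {
  cat("unitig_graph:", nrow(x$unitigs), "unitigs,", nrow(x$links), "links;",
      "total spelled length", sum(x$unitigs$length), "\n")
  invisible(x)
}

#' Spell a walk in the condensed unitig graph
#'
#' @param ug a `unitig_graph`.
#' @param walk integer vector of unitig ids along existing links.
#' @return the spelled amino-acid string of the walk.
#' @export
spell_unitig_walk <- function(ug, walk) {
  s <- ug$unitigs$sequence[walk[1L]]
  if (length(walk) > 1L) {
    key <- paste(ug$links$from, ug$links$to)
    for (i in seq_len(length(walk) - 1L)) {
      k <- match(paste(walk[i], walk[i + 1L]), key)
      if (is.na(k)) stop("walk does not follow condensed-graph links")
      nxt <- ug$unitigs$sequence[walk[i + 1L]]
      s <- paste0(s, substring(nxt, ug$links$overlap[k] + 1L))
    }
  }
  s
}
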