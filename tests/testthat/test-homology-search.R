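# Seeding, ungapped anchors, candidate-path DFS, banded alignment, E-values.

test_that("seed index holds exactly the X-free k-mer windows", {
  idx <- index_seeds(c("ACDEFG", "ACDXFGH", "ACD"), k = 6L)
  expect_equal(idx$hash[["ACDEFG"]], matrix(c(1L, 0L), 1L))
  expect_null(idx$hash[["ACDXFG"]])   # window with X skipped
  expect_null(idx$hash[["CDXFGH"]])
  expect_equal(idx$hash[["XFGH"]], NULL)  # short unitig contributes nothing
  sm <- seed_matches(idx, "ACDEFG")
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$unitig_id, 1L)
})

test_that("seed lookups equal brute-force k-mer window comparison", {
  set.seed(5)
  unis <- vapply(1:8, function(i) rand_pep1(sample(10:40, 1L)), character(1))
  idx <- index_seeds(unis, k = 6L)
  for (rep in 1:20) {
    q <- if (rep %% 2 == 0) rand_pep1(20L) else
      paste0(rand_pep1(7L), substring(sample(unis, 1L), 3L, 14L))
    sm <- seed_matches(idx, q)
    want <- 0L
    for (qp in seq_len(nchar(q) - 5L)) {
      kq <- substring(q, qp, qp + 5L)
      for (u in seq_along(unis)) {
        for (up in seq_len(max(0L, nchar(unis[u]) - 5L))) {
          if (substring(unis[u], up, up + 5L) == kq) want <- want + 1L
        }
      }
    }
    expect_equal(nrow(sm), want)
  }
})

test_that("ungapped extension returns the best diagonal segment with the seed", {
  m <- blosum62_matrix()
  # identical sequences: anchor spans everything, score = sum of self-scores
  s <- "MKVLITAAGH"
  a <- ungapped_extend(s, s, 2L, 2L, 6L, xdrop = 1000L)
  expect_equal(a$q_lo, 0L); expect_equal(a$q_hi, 10L)
  expect_equal(a$score, sum(diag(m)[match(strsplit(s, "")[[1]],
                                          rownames(m))]))
  expect_equal(a$diagonal, 0L)

  # heavily penalized flanks: the anchor interval equals the seed
  core <- "AAAAAA"
  q <- paste0("WW", core, "WW")
  u <- paste0("PP", core, "PP")
  a2 <- ungapped_extend(q, u, 2L, 2L, 6L)
  expect_equal(c(a2$q_lo, a2$q_hi), c(2L, 8L))
  expect_equal(a2$score, 6L * m["A", "A"])

  # random pairs vs exhaustive enumeration of segments containing the seed
  set.seed(19)
  for (rep in 1:60) {
    L <- sample(12:30, 1L)
    q <- rand_pep1(L); u <- rand_pep1(L)
    sp <- sample.int(L - 6L, 1L)
    a3 <- ungapped_extend(q, u, sp, sp, 6L, xdrop = 10000L)
    ps <- pair_scores_t(q, u)
    best <- -Inf
    for (lo in 1:(sp + 1L)) {
      for (hi in (sp + 6L):L) {
        best <- max(best, sum(ps[lo:hi]))
      }
    }
    expect_equal(a3$score, best)
  }
})

test_that("anchor filtering, deduplication and ordering are deterministic", {
  a <- data.frame(unitig_id = c(1L, 2L, 3L), score = c(12L, 40L, 25L),
                  q_lo = 0L, q_hi = 6L, u_lo = 0L, u_hi = 6L,
                  diagonal = 0L, query_pos = c(5L, 1L, 3L))
  out <- select_anchors(a, threshold = 20L)
  expect_equal(out$score, c(40L, 25L))
  expect_equal(select_anchors(a[0, ], 20L)$unitig_id, integer(0))
  # equal scores order by (unitig_id, query_pos); per-unitig best kept
  b <- data.frame(unitig_id = c(2L, 1L, 1L), score = c(30L, 30L, 28L),
                  q_lo = 0L, q_hi = 6L, u_lo = 0L, u_hi = 6L,
                  diagonal = 0L, query_pos = c(4L, 9L, 2L))
  out2 <- select_anchors(b, threshold = 20L)
  expect_equal(out2$unitig_id, c(1L, 2L))
  expect_equal(out2$score, c(30L, 30L))
})

test_that("anchor-ordered DFS reproduces the worked candidate-path example", {
  ug <- make_worked_graph()
  anchors <- data.frame(unitig_id = c(6L, 12L), score = c(200L, 150L),
                        q_lo = 25L, q_hi = 65L, u_lo = 0L, u_hi = 40L,
                        diagonal = 25L, query_pos = 25L)
  paths <- generate_candidate_paths(ug, anchors, query_length = 90L,
                                    slack = 0.2, max_paths = 64L)
  walks <- lapply(paths, function(p) p$unitigs)
  expect_true(list(c(3L, 6L, 9L)) %in% walks)
  expect_true(list(c(4L, 12L, 14L)) %in% walks)
  expect_true(list(c(7L, 12L, 14L)) %in% walks)
  expect_false(list(c(9L, 12L, 14L)) %in% walks)
  expect_length(walks, 3L)
  # every path contains its anchor unitig and follows links
  for (p in paths) {
    expect_true(p$anchor$unitig_id %in% p$unitigs)
    expect_silent(spell_unitig_walk(ug, p$unitigs))
  }
  # byte-identical on rerun
  paths2 <- generate_candidate_paths(ug, anchors, 90L, 0.2, 64L)
  expect_identical(paths, paths2)
})

test_that("a single anchor in a linear chain yields exactly one path", {
  ug <- make_worked_graph()
  anchors <- data.frame(unitig_id = 6L, score = 100L, q_lo = 25L, q_hi = 65L,
                        u_lo = 0L, u_hi = 40L, diagonal = 25L,
                        query_pos = 25L)
  paths <- generate_candidate_paths(ug, anchors, 90L)
  expect_length(paths, 1L)
  expect_equal(paths[[1]]$unitigs, c(3L, 6L, 9L))
  expect_equal(paths[[1]]$sequence, spell_unitig_walk(ug, c(3L, 6L, 9L)))
  expect_equal(paths[[1]]$anchor_offset, 35L)
})

test_that("candidate paths match exhaustive bounded enumeration on small graphs", {
  # brute force: same claiming rules, exhaustive walk enumeration
  brute <- function(ug, anchors, qlen, slack = 0.2) {
    ulen <- ug$unitigs$length
    claimed <- rep(FALSE, nrow(ug$unitigs))
    pending <- rep(TRUE, nrow(anchors))
    all_paths <- list()
    exts <- function(u, dir, need, walk) {
      nb <- if (dir == "right") ug$links[ug$links$from == u, c("to", "overlap")]
            else ug$links[ug$links$to == u, c("from", "overlap")]
      names(nb) <- c("u", "ov")
      nb <- nb[!claimed[nb$u] & !(nb$u %in% walk), , drop = FALSE]
      if (need <= 0 || nrow(nb) == 0L) return(list(integer(0)))
      sc <- rep(0, nrow(ug$unitigs)); sc[anchors$unitig_id] <- anchors$score
      nb <- nb[order(-sc[nb$u], nb$u), , drop = FALSE]
      out <- list()
      for (r in seq_len(nrow(nb))) {
        for (tail in exts(nb$u[r], dir, need - (ulen[nb$u[r]] - nb$ov[r]),
                          c(walk, nb$u[r]))) {
          out[[length(out) + 1L]] <- c(nb$u[r], tail)
        }
      }
      out
    }
    for (ai in seq_len(nrow(anchors))) {
      if (!pending[ai]) next
      pending[ai] <- FALSE
      a <- anchors[ai, ]
      if (claimed[a$unitig_id]) next
      nl <- ceiling(a$q_lo * (1 + slack)) - a$u_lo
      nr <- ceiling((qlen - a$q_hi) * (1 + slack)) -
        (ulen[a$unitig_id] - a$u_hi)
      lefts <- exts(a$unitig_id, "left", nl, a$unitig_id)
      rights <- exts(a$unitig_id, "right", nr, a$unitig_id)
      newu <- integer(0)
      visited <- a$unitig_id
      count <- 0L
      for (lw in lefts) for (rw in rights) {
        if (count >= 64L) break
        w <- c(rev(lw), a$unitig_id, rw)
        all_paths[[length(all_paths) + 1L]] <- w
        newu <- union(newu, w)
        count <- count + 1L
      }
      visited <- union(visited, unlist(c(lefts, rights)))
      claimed[newu] <- TRUE
      pending[pending & anchors$unitig_id %in% visited] <- FALSE
    }
    unique(all_paths)
  }
  set.seed(29)
  for (rep in 1:10) {
    n <- sample(6:12, 1L)
    useq <- vapply(seq_len(n), function(i) rand_pep1(30L), character(1))
    # random sparse DAG-ish links with fixed 5-residue junctions: rewrite
    # sequences so junctions are consistent
    links <- list()
    for (u in seq_len(n - 1L)) {
      for (v in (u + 1L):n) {
        if (stats::runif(1) < 0.25) {
          substr(useq[v], 1L, 5L) <- substring(useq[u], 26L, 30L)
          links[[length(links) + 1L]] <- data.frame(from = u, to = v,
                                                    overlap = 5L)
        }
      }
    }
    if (length(links) == 0L) next
    links <- do.call(rbind, links)
    # junction rewrites may collide; keep only consistent links
    ok <- substring(useq[links$to], 1L, 5L) ==
      substring(useq[links$from], 26L, 30L)
    links <- links[ok, , drop = FALSE]
    ug <- structure(list(
      unitigs = data.frame(unitig_id = seq_len(n), sequence = useq,
                           length = nchar(useq), n_members = 1L),
      members = NULL, links = links), class = "unitig_graph")
    na <- sample(1:3, 1L)
    aun <- sample(seq_len(n), na)
    anchors <- data.frame(unitig_id = aun,
                          score = sort(sample(30:90, na), decreasing = TRUE),
                          q_lo = 20L, q_hi = 50L, u_lo = 0L, u_hi = 30L,
                          diagonal = 20L, query_pos = 20L)
    got <- lapply(generate_candidate_paths(ug, anchors, 70L), `[[`, "unitigs")
    want <- brute(ug, anchors, 70L)
    expect_equal(got, want)
  }
})

test_that("banded Smith-Waterman matches independent DP oracles", {
  m <- blosum62_matrix()
  s <- "MKVLITAAGH"
  aln <- banded_smith_waterman(s, s)
  expect_equal(aln$score,
               sum(diag(m)[match(strsplit(s, "")[[1]], rownames(m))]))
  expect_equal(aln$edit, "10M")
  expect_true(edit_consistent(aln, s, s))

  # full band equals the unrestricted full-matrix oracle
  set.seed(37)
  for (rep in 1:120) {
    a <- rand_pep1(sample(10:45, 1L))
    b <- if (rep %% 3 == 0) rand_pep1(sample(10:45, 1L)) else {
      # related pair: mutate a few residues to exercise real alignments
      ch <- strsplit(a, "")[[1]]
      pos <- sample(seq_along(ch), max(1L, length(ch) %/% 6L))
      for (p in pos) ch[p] <- sample(AA20_T, 1L)
      paste(ch, collapse = "")
    }
    aln <- banded_smith_waterman(a, b)
    expect_equal(aln$score, biostrings_sw(a, b))
    expect_true(edit_consistent(aln, a, b))
  }
  # spot-check against a second, hand-rolled R oracle
  for (rep in 1:10) {
    a <- rand_pep1(25L); b <- rand_pep1(25L)
    expect_equal(banded_smith_waterman(a, b)$score, r_sw_score(a, b))
  }
})

test_that("widening the band never decreases the score", {
  set.seed(41)
  for (rep in 1:40) {
    a <- rand_pep1(30L); b <- rand_pep1(30L)
    scores <- vapply(c(1L, 3L, 6L, 12L, 30L), function(w) {
      banded_smith_waterman(a, b, band_width = w, band_center = 0L)$score
    }, integer(1))
    expect_true(all(diff(scores) >= 0L))
    expect_equal(scores[5L], biostrings_sw(a, b))
  }
})

test_that("disjoint high-penalty sequences align to nothing", {
  aln <- banded_smith_waterman("WWWWWW", "PPPPPP")
  expect_equal(aln$score, 0L)
  expect_equal(aln$align_cols, 0L)
  expect_error(banded_smith_waterman("", "AAA"), "non-empty")
})

test_that("E-values follow the Karlin-Altschul closed form", {
  # direct arithmetic oracle
  expect_equal(evalue_of(50, 100, 1e6),
               0.041 * 100 * 1e6 * exp(-0.267 * 50))
  # monotone decreasing in score; vanishing at large score
  ev <- evalue_of(c(10, 20, 40, 80, 400), 100, 1e6)
  expect_true(all(diff(ev) < 0))
  expect_lt(ev[5], 1e-38)
  # linear in database size
  expect_equal(evalue_of(50, 100, 2e6), 2 * evalue_of(50, 100, 1e6))
  expect_error(evalue_of(50, 0, 1e6), "length")
  expect_error(evalue_of(-1, 100, 1e6), "score")
})

test_that("a verbatim planted query is self-recovered end to end", {
  set.seed(43)
  com <- generate_community(n_genomes = 2L, genome_length = 320L,
                            n_queries = 1L, homolog_identity = 1.0,
                            seed = 43L, query_length = 100L)
  sh <- shred_reads(com, read_length = 30L, coverage = 12, error_rate = 0,
                    seed = 44L)
  idx <- grasp_index(sh$reads, sh$ids, config = grasp_config(block_size = 400L))
  hits <- assemble_homologs(com$queries[1L], idx,
                            query_id = com$query_ids[1L])
  expect_gt(nrow(hits), 0L)
  expect_true(any(grepl(com$queries[1L], hits$sequence, fixed = TRUE)))
})

test_that("a query sharing no seed with any unitig finds nothing", {
  reads <- c("MKVLITAAGH", "ITAAGHWQER", "GHWQERSPLK")
  idx <- grasp_index(reads)
  hits <- assemble_homologs("CCCCCCCCCCCC", idx)
  expect_equal(nrow(hits), 0L)
})
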