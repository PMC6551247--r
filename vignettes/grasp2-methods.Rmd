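---
title: "Gene-centric assembly and homolog search for short peptide reads"
author: "grasp2r"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric assembly and homolog search for short peptide reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasp2r)
```

## The problem

Functional annotation of a metagenome usually proceeds either by whole-sample
de novo assembly followed by database search, or by searching each read
individually. Both routes lose signal: assemblies of complex communities are
fragmentary and chimeric, while a 30-residue peptide read carries too little
information for reliable remote-homology detection. Gene-centric assembly
inverts the problem: given one reference protein, assemble *only* the reads
that belong to its homologs, then use the assembled contigs as templates to
recruit the individual reads. The contig carries the pooled signal of all its
reads, so reads that share no seed with the reference are still recovered
through their overlap neighbours.

`grasp2r` implements this "filter, traverse, then align" strategy for
short-peptide read sets (reads called from ~100 bp fragments, typically 20-60
residues, 20-letter alphabet plus `X`).

## Indexing: blockwise BWT and the string graph

The read set is partitioned into blocks (input order, `block_size` reads per
block) and a multi-string Burrows-Wheeler transform with FM-index rank/count
structures is built per block. Each read is terminated by its own sentinel;
sentinels sort below every residue, and ties between sentinel-terminated
suffixes are resolved by read order, making construction fully deterministic.
Suffix sorting uses R's stable radix string sort behind a single interface --
at the scale this reference implementation targets (10^3-10^5 reads) an
induced-sorting algorithm would add complexity without changing semantics.
Rank tables are dense cumulative counts, so block memory is
O(alphabet x residues); `block_size` bounds that footprint.

Overlap detection walks each read's suffixes backward through every block:
at suffix length m, the BWT rows whose character is the sentinel are exactly
the reads whose *prefix* equals that suffix, so keeping the last hit per
target read yields the maximal overlap for every ordered pair in one scan.
Only proper overlaps with `l <= m < min(len(source), len(target))` become
edges (default `l = 10`); full-length matches are containment-shaped and are
handled by a separate *within-block* containment scan (each read searched in
its own block; equal-length duplicates resolve with the lower read index as
container). Containments that span two blocks are deliberately *not*
detected -- that is the price of blockwise indexing -- and the resulting
redundant nodes are repaired on the graph instead:

* **Transitive reduction** removes an edge v->w whenever a neighbour u
  explains it exactly (label(v->w) = label(v->u) + label(u->w)), marked
  against the original edge set so the sweep is order-independent.
* **Bubble removal** deletes one branch of two node-disjoint paths between
  the same node pair *only when their spelled sequences are identical*. The
  branch with fewer member reads loses; on ties the branch whose minimum
  read index is larger loses. A branch may be a bare edge (zero intermediate
  nodes), in which case the deletion is an edge deletion. Paths that differ
  in a single residue are both kept -- this is what preserves SNPs from
  low-abundance genomes, and it is the property the polymorphism-retention
  tests pin down.
* **Tip trimming** removes a two-node dead-end (r, t) only when its spelled
  sequence is contained in the spelling of another path through r with at
  least three nodes (measured on the uncollapsed read graph). Orphan
  two-node components are never trimmed.

Bubble and tip passes alternate to a joint fixed point (`clean_graph()`);
both are monotone in node/edge counts and idempotent at their fixed points.
Unbranched paths are then collapsed into unitigs carrying their spelled
sequence and member-read placements; remaining edges become condensed-graph
links labelled with the junction overlap, so spelling a unitig walk equals
spelling the underlying read path.

The block-partition robustness test asserts the net effect: unitig spelling
sets from 1-block and 4-block indexing are identical after cleanup.

## Search: anchors, candidate paths, banded alignment

Every `k`-mer of every unitig (default `k = 6`, windows containing `X`
skipped) is hash-indexed at build time. For a reference protein, each shared
seed is extended along its diagonal without gaps; the extension keeps the
running best segment, and an X-drop rule (default X = 20) bounds the scan,
so the returned anchor is the best-scoring ungapped segment containing the
seed under BLOSUM62. Anchors below `anchor_threshold` (default 25) are
dropped; the rest are deduplicated per unitig and sorted by descending score
(ties by unitig id, then query position).

Candidate homologous paths are generated by depth-first search from each
surviving anchor, toward both termini, until the spelled length on each side
reaches the query-proportional target (`query_length * (1 + path_slack)`,
slack 0.2, apportioned by the anchor's position on the query). Two
suppression rules keep the path set non-redundant, and their interaction is
pinned by a worked-example test: anchors reached during any DFS are removed
from the pending list, and unitigs already claimed by an earlier anchor's
paths may not be entered. Branch points yield one path per left/right walk
combination, capped at `max_paths_per_anchor` (64), explored in order of
descending next-unitig anchor score.

Each candidate path is aligned to the reference with a banded
Smith-Waterman-Gotoh kernel (C++): affine gaps costing `open + g * extend`
(defaults 11/1, the conventional BLOSUM62 pairing), band of half-width
`max(40, 0.2 * query_length)` centred on the source anchor's diagonal. With
a full band the kernel equals unrestricted local alignment, which is how the
tests validate it against an independent full-matrix implementation.
Traceback prefers gap-open on ties so gaps are as short as the optimum
allows. Significance uses the Karlin-Altschul form
`E = K * m * n * exp(-lambda * S)` with configurable gapped constants
(defaults lambda = 0.267, K = 0.041, calibrated to the comparator family of
scoring parameters, not fitted here); paths with `E <= evalue_cutoff`
(default 1e-3) are emitted as homologous contigs.

## Recruitment

Reads are mapped back onto the contigs with the same seeding machinery
(exact 6-mers against the contig set) followed by banded verification. A
placement is accepted when identity (matches / alignment columns) reaches
`min_identity` (0.9) over at least `min_span` (0.8) of the read, *and* the
placement overlaps the contig's query-aligned interval by more than
`min_hit_overlap` (0.6) of the read length. The last rule matters because
candidate paths are deliberately spelled ~20% longer than the reference:
reads landing on the non-homologous flanks are not homolog calls, and
without the rule they dominate the false positives. Each read is assigned to
at most one (query, contig): most significant contig E-value first, then
smaller query id, then higher identity.

## The synthetic benchmark generator

`generate_community()` and `shred_reads()` emulate, directly in peptide
space, a benchmark built from real genomes shredded at 10X / 100 bp / 1%
error and translated to peptides: random background proteomes (SwissProt-like
residue frequencies), homolog copies planted by BLOSUM62-biased substitution
to a target identity (default 0.75, matching a ~77%-similar community; the
realized identity is exact by construction), fixed-length reads (33 aa ~
100 bp / 3) at uniform random starts to the target depth, and independent
per-residue substitution errors. Reads are labelled `homolog`,
`non_homolog`, or `boundary` (straddling a planted-region endpoint);
boundary reads are excluded from every evaluation count, mirroring the
benchmark labelling rule. Everything is a pure function of its seed.

What the generator does *not* emulate -- and hence what passing tests do not
show about real data: indel sequencing errors and chimeric reads, gene-calling
(frame) errors, compositional bias and repeats in real proteomes, uneven
coverage, and homologs diverged by insertion/deletion rather than
substitution. Recall/precision measured here characterize the machinery
under controlled divergence, not field performance.

## Evaluation

`score_predictions()` counts, per query and pooled, TP (homolog reads
recruited to their query), FP (recruited reads that are not that query's
homologs), FN (homolog reads missed), always excluding boundary reads;
precision is TP/(TP+FP), recall TP/(TP+FN), and undefined ratios are
reported as `NA`, never coerced. Pooled metrics are micro-averaged by
default (pooled counts), with macro-averages also available, since either
convention is defensible. `roc_over_cutoffs()` sweeps E-value cutoffs
(default 10^6 down to 10^-10) and recomputes one precision/recall point per
cutoff; nested prediction sets make recall monotone along the sweep.

## Numerical and design choices

* `X` residues are kept in sequences, but match nothing in FM-index
  patterns and never seed; alignment scores them by their BLOSUM62 column.
* Exact duplicate reads: the lower index is the container.
* Seeding can optionally use a Murphy-style 10-letter reduced alphabet
  (`reduced_alphabet = TRUE`); the default is the exact alphabet, since the
  reduction trades specificity for seed sensitivity and the defaults aim at
  reproducible reference behaviour.
* The on-disk index stores reads, per-block BWT + suffix-array samples,
  unitig GFA + placements and the config; rank tables are recomputed
  deterministically on load, so a reloaded index equals a rebuilt one.
* Degenerate inputs: empty read sets, non-alphabet characters, empty
  alignment inputs and out-of-range FM intervals raise explicit errors; an
  `l` above every read length warns and returns an empty overlap set.

## Problem sizes

The shipped tests and `scripts/acceptance.R` run at desk scale, chosen so
the whole suite completes in minutes while every property is exercised at
meaningful density: communities of 5 x 600-residue proteomes with two
150-residue references (about 900 reads at 10X), read sets of up to a few
hundred reads for the oracle comparisons, and 1000 random pairs for the
alignment equivalence check. The acceptance script pools three replicate
communities per seed.

## Known limitations

* Single-threaded reference implementation; dense rank tables rather than
  compressed structures, so very large read sets need proportional memory.
* E-value calibration is configuration, not a fitted statistic; absolute
  E-values are comparator-style, while the default cutoff behaves sensibly
  on the synthetic benchmark.
* Bubble and tip searches bound their path enumeration (depth 10, capped
  path counts); pathological graphs denser than anything a read set at these
  conditions produces could in principle leave redundancy unremoved.
* Recruitment verifies with gapped banded alignment; whether the original
  tool maps reads with gaps is unstated, so gapped verification is the more
  permissive choice.

## A worked call

```{r example, eval = FALSE}
com <- generate_community(seed = 1)           # 5 genomes, 2 planted queries
sh  <- shred_reads(com, seed = 2)             # 33-aa reads, 10X, 1% error
idx <- grasp_index(sh$reads, sh$ids,
                   config = grasp_config(block_size = 250))
hits <- assemble_homologs(com$queries[1], idx, com$query_ids[1])
rec  <- recruit(hits, sh$reads, sh$ids)
score_predictions(rec, sh$truth)
```
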