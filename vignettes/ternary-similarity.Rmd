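---
title: "Ternary similarity constraints for structural classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ternary similarity constraints for structural classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternclust)
```

## The model

A protein domain is modeled as an *item*: an ordered set of parts (residues
or residue blocks), identified inside the package by their integer position
in the item. A pairwise structural alignment of items $o$ and $o'$ is a
one-to-one mapping $M(o, o')$ of parts of $o$ onto parts of $o'$ together
with a significance score. `ternclust` never computes alignments — they are
inputs, one row per mapped pair in a simple TSV — and never touches 3D
coordinates.

Two items are *similar*, and joined by an edge of the similarity graph $G$,
when the alignment is significant. Two criteria are supported, both
inclusive:

* `criterion = "score"`, `score >= t_o` — the pipeline default with
  `t_o = 7`, matching the z-score cutoff a rapid structural aligner reports;
* `criterion = "count"`, `|M(o, o')| >= t_o` — the abstract mapped-pair-count
  definition, useful with toy part-identity alignments.

The two are genuinely different thresholds on different scales; exposing
both and defaulting to the score criterion was a deliberate choice, since
real aligner output carries a score while the count criterion makes small
hand-built examples exact.

Pairwise similarity is blind to *which* parts are shared. The **centered
ternary similarity** repairs this: for adjacent edges $(o', o)$ and
$(o, o'')$, let $P_{o',o''}(o)$ be the parts of the central item mapped in
both alignments. The constraint holds iff

$$|P_{o',o''}(o)| \;\ge\; T \cdot \min(|M(o,o')|,\,|M(o,o'')|),
\qquad T \in [0,1],$$

again inclusive, so an overlap exactly at the bound satisfies it. At $T = 0$
every check passes vacuously; at $T = 1$ the smaller alignment must be fully
contained in the overlap. The constraint cannot be expressed through any
combination of pairwise (must-link / cannot-link) constraints: it is
irreducibly ternary, and a 3-clique whose edges run through three pairwise
distinct parts violates all three of its centered checks for every $T > 0$
(`case_fixture("property1")`).

## The reduction

Constraint checking and edge removal both live on the labeled line graph
$L(G)$: vertices are edges of $G$; two line vertices are joined when the
edges share an endpoint, and since $G$ has no parallel edges that endpoint —
the center — is unique (asserted during construction). Line vertices keep
their item-pair labels, which makes the transformation invertible; removing
a line vertex is exactly removing an edge of $G$, and connected components
of $G$ and $L(G)$ correspond one-to-one when $G$ has no isolated vertices
(isolated items are dropped, and reported, before any processing).

Marking evaluates every line edge's centered check at threshold `t`. The
greedy heuristic then works on the subgraph induced by marked edges only:

1. find the maximal degree $\Delta$ among vertices with marked incidences;
2. remove *all* vertices attaining $\Delta$ in one batch;
3. recompute degrees and repeat until no marked edge remains.

The removal set is a vertex cover of the marked subgraph — near-minimal, not
minimal; exact minimum vertex cover is NP-hard and the greedy
highest-degree-first rule maximizes marked edges cleared per vertex spent.
Design choices worth recording:

* **Batch removal.** All max-degree vertices go in one iteration, with
  degrees recomputed only between iterations. A `one_at_a_time = TRUE`
  variant implements the stricter serial greedy for comparison; the batch
  rule is the default because it is the natural reading of computing the
  batch once per loop. A consequence: a marked edge between two degree-1
  vertices loses *both* endpoints.
* **Only marked-incident vertices are candidates.** A line vertex with a
  huge unmarked degree is never touched.
* **Determinism.** Vertex labels are canonical sorted pairs and batches are
  processed in sorted order, so traces (`tidy()` on the result) are
  reproducible. Degree ties need no tie-break under the batch rule; the
  serial variant takes the smallest label.
* **Certification.** Every reduced graph is re-checked exhaustively (every
  length-2 path) before being returned; `verify_ternary()` is the same
  check exposed as an oracle.
* **No post-processing.** When a component splits, fragments — even
  single-edge ones — are kept as they are; no reconnection or pruning is
  attempted.

Marking is monotone in `t` (inclusive arithmetic: any edge marked at $t_1$
is marked at every $t_2 \ge t_1$), but the *trace* of the heuristic is not
monotone in any useful sense — batch removals can make $\Delta$ fluctuate —
so only cover-ness and termination are asserted, not trace shape.

## Clustering and evaluation

The built-in MCL implementation follows the standard
expansion–inflation–prune scheme on sparse column-stochastic matrices:
self-loops of weight 1 are added before normalization; expansion is the
matrix square (power configurable); inflation raises entries to $I$ and
renormalizes; entries below `1e-5` are pruned and columns renormalized;
iteration stops when the matrix changes by less than `1e-8` (max absolute
entry) or at 200 iterations, the latter with a warning and the current
interpretation. Adjacency is binary by default — nothing in the method
requires score-weighted flow — with `weighted = TRUE` available for
exploration. Attractors (nodes retaining flow on their own column) label
clusters; the rare node attracted by several attractors is assigned to its
lexicographically smallest attractor, keeping the output a deterministic
partition. Clusters never span connected components, so running MCL on the
whole graph at once is equivalent to per-component runs.

Partitions are compared by pair counting over unordered item pairs —
TP, FN, FP, then Recall, Precision and Jaccard — computed from the cluster
contingency table and property-tested against brute-force enumeration. True
negatives are ignored by design: with thousands of mostly-unrelated domains
they swamp every other count. Conventions: when both partitions have zero
co-classified pairs all three ratios are 1 (two all-singleton partitions
agree perfectly); a zero denominator otherwise yields 0. Items that lose
their last edge during reduction re-enter the predicted partition as
singletons before evaluation — singletons add no false-positive pairs and
keep both partitions on the same universe, which is the graph's item set
after isolated-item removal (items never similar to anything are outside
the evaluation altogether).

## The synthetic benchmark

`synthetic_spec()` / `generate_benchmark()` emulate exactly the situation
the reduction corrects. Each family has a motif of `parts_per_motif = 40`
parts — a realistic alignment length, matching the scale of the worked
73/75-residue example — shared by all `items_per_family = 5` members;
`n_linkers = 2` modular items carry two family motifs and align to both
families. Any two items sharing a motif get an alignment covering the full
shared motif with score drawn from a normal (sd 1, truncated at 0) around
`score_signal = 9`; motif-unrelated pairs get, with probability
`noise_pair_rate = 0.05`, a spurious few-position alignment around
`score_noise = 5`. Signal and noise straddle the score cutoff of 7 the way
a well-separated aligner score distribution would, so an occasional noise
edge survives filtering — which is what the flexible-similarity failure
mode looks like in practice. Items also carry 8 private parts so that
alignments never cover whole items. In the reference partition each linker
is assigned to its first-listed family, mirroring a flat reference that
gives every domain exactly one family; generation is fully reproducible
from `seed`.

What the generator does *not* emulate: 3D geometry, secondary structure,
partial or shifted motif alignments, aligner-specific score distributions,
or multi-level (superfamily/fold) structure. Passing tests on this benchmark
show that the pipeline separates planted modular structure under score
noise; they do not show recovery rates on real aligner output, where motif
boundaries are fuzzy and overlaps are partial rather than all-or-nothing.

`case_fixture()` complements the generator with exact toy constructions:
the linker bridge (`case1`), the no-common-part clique (`case2`), the
non-transitive-but-common-part triple (`case3`), the clique counterexample
(`property1`), and the three-domain worked example with alignment
cardinalities 73 and 75 sharing 35 central positions (`figure6`), whose
centered similarity is $35/73 \approx 48\%$ and fails $T = 0.65$. One
boundary subtlety in `case3`: a rule of "at least half of the shorter item"
would, at these part counts, admit the (o1, o3) edge through its single
shared part (1 of 2 parts is exactly 50%); the fixture's intent is that
such a borderline similarity is *rejected*, so it instantiates the rule as
strictly-more-than-half — with these sizes, the inclusive count threshold
`t_o = 2`.

## Grids, sizes and limitations

`run_pipeline()` sweeps `t_grid` (default 0.05–0.95 in steps of 0.05, plus
a no-reduction baseline reported as `t = NA`) crossed with
`inflation_grid` (default 1.2–2.0 by 0.1 union 2.0–3.0 by 0.2) and returns
one tidy row per combination with reduced-graph statistics (edges, ICC
count and sizes), clustering granularity, and pair-counting metrics. The
packaged benchmark (12 items, ~42 edges) keeps the full 20 × 14 grid — 280
reductions-plus-clusterings — comfortably in the tens of seconds; the
property suites use graphs of 5–18 items, and the exhaustive
minimum-vertex-cover comparison is restricted to marked subgraphs on at
most 10 line vertices, where enumeration is exact.

Known limitations: the greedy cover can overshoot the minimum (tests assert
only `>=` against the exhaustive optimum); the reduction assumes one
alignment per pair (an aligner reporting alternative alignments must be
pre-filtered to its best); thresholds are global, not per-edge; and the
evaluation is flat — hierarchical classifications are compared at a single
level chosen by the caller.
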