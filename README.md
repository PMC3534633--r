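# ternclust

Automatic classification of protein domain structures from pairwise
structural-alignment mappings, with a ternary-similarity graph reduction
applied before clustering.

## The problem

Pairwise structural similarity is not enough to define a structural family.
A *modular* domain carrying two motifs is genuinely similar to members of two
different families; in the similarity graph it becomes a high-degree linker,
and connectivity-based clustering will happily merge the two families around
it even though their members share no substructure at all. Transitivity does
not help either: three domains can be pairwise similar through three
*different* shared parts, forming a clique whose members have nothing in
common.

`ternclust` is for structural bioinformaticians who have a table of pairwise
alignments (e.g. from a fast 3D aligner reporting, for each significant pair,
a z-score and the one-to-one residue mapping) and want flat structural
families in which every linked triple of domains shares a common motif.

## The method

Let an item *o* be a set of parts (residues/blocks), and *M(o, o′)* the
mapped pairs of a pairwise alignment. The similarity graph *G* keeps an edge
(o, o′) when the alignment is significant (score ≥ T_O, default z-score ≥ 7;
a mapped-pair-count criterion is also available).

For two adjacent edges (o′, o) and (o, o″) the **centered ternary
similarity** holds when the parts of the central item mapped in *both*
alignments are a large enough fraction of the smaller alignment:

    |P_{o′,o″}(o)|  ≥  T · min(|M(o, o′)|, |M(o, o″)|),     T ∈ [0, 1]

On the labeled line graph *L(G)* (vertices = edges of G, joined when
adjacent, each line edge annotated with its center), every line edge
violating the constraint is *marked*. A greedy heuristic then repeatedly
deletes — in one batch per iteration — all line vertices of maximal degree in
the marked subgraph, until no marked edge remains. Because removing a line
vertex is exactly removing the corresponding edge of G, the surviving line
graph inverts to a reduced graph **G_T** in which *every* ternary constraint
holds. G_T is clustered with a built-in Markov Cluster (MCL) algorithm
(inflation *I* controls granularity), and partitions are scored against a
reference classification by pair counting: Recall = TP/(TP+FN),
Precision = TP/(TP+FP), Jaccard = TP/(TP+FN+FP).

## Worked example

The packaged synthetic benchmark plants two families of five domains, each
family sharing a 40-part motif, plus two modular linkers carrying both
motifs, and simulates aligner output (signal scores around 9, spurious noise
around 5, cutoff 7):

```r
library(ternclust)

bench <- generate_benchmark(synthetic_spec())
graph <- drop_isolated(build_graph(bench$mappings, t_o = 7))
graph
#> <tern_graph> 12 items, 42 edges

red <- reduce_graph(graph, t = 0.65)
red
#> <tern_reduction> t = 0.65: removed 20 edges in 1 iterations;
#>   G_T has 12 items, 22 edges (0 items absent)
```

Without the reduction, MCL at inflation 2 funnels everything through the
linkers into one cluster; with it, the families separate:

```r
base <- mcl_cluster(graph, inflation = 2)
partition_metrics(bench$truth$partition, base)
#>      tp    fn    fp recall precision jaccard n_items n_clusters
#> 1    31     0    35      1     0.470   0.470      12          1

part <- mcl_cluster(red$graph, inflation = 2)
partition_metrics(bench$truth$partition, complete_partition(part, graph$items))
#>      tp    fn    fp recall precision jaccard n_items n_clusters
#> 1    21    10     0  0.677         1   0.677      12          3
```

Precision rises from 0.47 to 1 (no false co-classifications remain); the
residual FN pairs are the linkers, which the reference must assign to a
single family. `run_pipeline()` sweeps the full T × I grid and returns one
tidy row per combination; `plot_pr_curve()` and `plot_granularity()` chart
the report.

A thin command-line driver mirrors the stages
(`exec/ternclust simulate | build-graph | reduce | cluster | evaluate |
pipeline`).

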