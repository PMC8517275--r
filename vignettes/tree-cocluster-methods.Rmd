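---
title: "Tree-constrained co-clustering of binary accessibility matrices: methods"
author: "treecoclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-constrained co-clustering of binary accessibility matrices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treecoclust)
```

## The problem

Bulk ATAC-seq across a panel of cell types ends, after peak calling, in a
binary accessibility matrix $M$: one row per genomic locus, one column per
cell type, $M_{lc} = 1$ when locus $l$ was called accessible in cell type
$c$. When the cell types are related by a known differentiation tree — as
hematopoietic cell types are — the scientific question is how much of the
structure of $M$ reflects that tree: which groups of loci open and close
together, in which coherent parts of the tree, and how much of the
cell-type-associated variation a small grid of (locus cluster) × (cell-type
cluster) blocks can capture.

`treecoclust` implements that co-clustering analysis end to end:

1. **Matrix construction** from per-cell-type narrowPeak files: summit-centred
   500-bp windows, a greedy master list of non-overlapping loci, and binary
   intersection calls.
2. **Locus clustering**: a similarity graph whose edges join loci with an
   improbably large number of shared accessible cell types (hypergeometric
   upper tail, Benjamini–Hochberg edge threshold), clustered with Louvain.
3. **Cell-type clustering under the tree constraint**: local search over
   *cut specifications*, which encode exactly the column partitions whose
   every block *respects* the tree.
4. **Model summaries**: co-cluster means $\tilde M^{(k)}$, the two-state
   restriction $\tilde M^{(k)}_{i/a}$, and ANOVA $R^2$ decompositions.
5. **Enrichment**: TF-motif enrichment over accessibility co-clusters with a
   permutation FDR, and ChIP-seq summit counts scaled against a uniform null.

## Respecting the tree

A set $U$ of cell types *respects* the tree when its induced subgraph is
connected, or when the roots of its connected components are all children of
one common parent. The second clause matters biologically: a progenitor's
children may share an accessibility program that the progenitor itself does
not show, so clusters must be allowed to exclude the parent while keeping its
children together.

Every partition of the tree into $k$ respecting blocks can be written as
$k - 1$ *cut groups*: a cut vertex $p_i$ together with a set of its children;
severing those child edges carves the tree, each group's components union
into one cluster, and the component holding the root is the $k$-th cluster.
Cut vertices may repeat across groups; members may not. `respects_tree()`,
`partition_from_cutspec()` and `enumerate_tree_partitions()` expose this
algebra, and the test suite verifies by exhaustive enumeration on small trees
that cut specifications reach *exactly* the partitions whose blocks all
respect the tree.

## The objective and its optimisation

With locus clusters $W_j$ fixed and a column partition $U_1,\dots,U_k$, the
approximation $\tilde M^{(k)}$ replaces each entry by its co-cluster mean,
and fit is the squared Frobenius residual
$\lVert M - \tilde M^{(k)}\rVert_F^2$. For binary $M$ this collapses to
$\sum_{j,i}(S_{ji} - S_{ji}^2/m_{ji})$ with $S_{ji}$ the block sum and
$m_{ji}$ the block size, so a cache of per-(locus cluster, column) sums makes
every candidate partition an $O(Jk)$ evaluation (`fit_cache()`).

`optimize_tree_partition()` minimises this objective by local search over cut
specifications, alternating two move families until a full double cycle
yields no improvement:

* **cut-group moves** at each cut vertex: add one unclaimed child to a group,
  remove a member (if the group stays nonempty, so $k$ is conserved), or
  transfer a member between two groups of the same vertex;
* **cut-vertex moves** for each pair $(v, v')$: delete one group of $v$ and
  open a singleton group at $v'$ with one of its unclaimed children.

Acceptance is *strictly* improving, taking the best candidate per vertex (or
vertex pair); ties keep the incumbent. Cycles follow tree preorder so runs
are reproducible. The search restarts from 20 random initial specifications
(restart $r$ seeds the RNG with `seed + r - 1`); each start draws $k-1$
distinct non-leaf cut vertices and gives each its full set of unclaimed
children.

### Known limitation: two-move traps

Strictly improving moves cannot pass through a worse intermediate. A
recurring trap: the search settles on cutting the single edge *above* a
vertex $v$ where the better solution cuts all of $v$'s child edges, leaving
$v$ with its parent. Converting one into the other requires a cut-vertex move
to a one-child group first — typically worse — before the remaining children
are added back one at a time. On small trees (≤ 10 nodes, $k \le 4$) the
20-restart search matches the exhaustively enumerated optimum in well over
95% of random instances, but on 30-node trees with $k = 5$ and realistic
noise it reaches the planted optimum in only a quarter to a half of runs
(depending on row-label quality), and the one-node-off local optima it
returns are confirmed stationary by exhaustive neighbourhood enumeration. Users who need the exact optimum on small trees
should call `enumerate_tree_partitions()`; on large trees, more restarts
help (the trap rate falls with restart count) but do not vanish.

## Locus clustering

For two rows with $n$ and $N$ ones over $C$ columns sharing $s$ ones, the
null that one row's columns are permuted makes $s$ hypergeometric
(population $C$, $N$ successes, $n$ draws); `pair_pvalue()` is the upper
tail $P(S \ge s)$. Edges are placed at the Benjamini–Hochberg step-up cutoff
over all $\binom{L}{2}$ pairs (`edge_threshold()`); because the p-value
depends only on $(n, N, s)$, the scan tabulates pairs by that triple with
chunked BLAS cross-products rather than looping over pairs, and edge
extraction uses a minimal-shared-count table per $(n, N)$. A $10^4 \times 78$
matrix takes seconds on one CPU. Louvain (igraph, resolution 1, seeded)
clusters the graph; only clusters with ≥ 30 loci enter the co-clustering, and
loci accessible in ≤ 2 cell types are set aside beforehand as cell-specific.

The number of cell types bounds the resolution of this test: with 78 columns
two loci sharing a 6-column block are overwhelming evidence, with 30 columns
they are marginal. The edge FDR is therefore an operating point, not a
universal constant, and no fixed value transfers between panels.
`choose_edge_fdr()` encodes the standard selection procedure: sweep a grid
from the conservative end and take the first FDR at which at least ~70% of
loci connect to something — the regime in which large-panel analyses
operate. Even so, two locus clusters whose accessibility states differ only
in one small cell-type cluster generate between-cluster edge densities close
to their within-cluster densities on small panels, and Louvain at resolution
1 merges them; this is a resolution limit of the binary similarity graph,
not of the clustering step.

## Two-state model and ANOVA

Within each locus cluster the co-cluster means are restricted to two values,
an inaccessible and an accessible state. Given the state assignment the
optimal values are entry-weighted side means, and the optimal assignment is
contiguous in the sorted means, so `two_state_split()` scans the $k - 1$
split points — an exact 1-D weighted 2-means, verified against brute force
over all $2^k$ assignments. Ties prefer fewer accessible clusters; a cluster
with all means equal is degenerate and reported all-inaccessible with a
flag. Each locus cluster then yields an *accessibility co-cluster*: its loci
paired with the union of accessible-state cell types.

`cocluster_anova()` reports, per locus cluster,
$R^2_{\text{total}} = 1 - \lVert M - \tilde M\rVert^2 / \lVert M - \mu\rVert^2$
and the cell-type component
$R^2_{\text{cell}} = 1 - \sum_c (\bar M_{\cdot c} - \tilde m_c)^2 /
\sum_c (\bar M_{\cdot c} - \mu)^2$, where $\bar M_{\cdot c}$ are within-
cluster column means. $R^2_{\text{cell}}$ is exactly 1 under singleton
column clusters and exactly 0 under the single-cluster partition — the two
analytic identities `scripts/acceptance.R` recomputes. Overall values are
unweighted averages over locus clusters; constant clusters (zero
denominator) report 1 and are flagged.

## Enrichment

Motif enrichment compares, for each accessibility co-cluster and motif, the
average per-cell-type fraction of accessible co-cluster loci carrying the
motif ($r$) against the same quantity on the complement block ($n$), through
the score $(r - n)/(r + n)$. The global call cutoff comes from permutations
that shuffle the locus labels of the motif matrix — breaking the locus–motif
association while preserving per-motif frequencies and $M$ — choosing the
smallest cutoff whose estimated FDR (mean permuted exceedances over observed
exceedances) is at or below the target. Enrichment analyses are meant to run
on TSS-distal loci only (`filter_distal()`, > 3,000 bp from a TSS measured
from the locus midpoint), since promoter-proximal loci are accessible nearly
everywhere.

ChIP-seq validation counts loci whose peak summit falls inside the 500-bp
locus window, per locus cluster, scaled by the expected count under uniform
placement; clusters with scaled count > 1 are enriched, and the overlap
between enriched clusters and the clusters accessible in the ChIPped cell
type is tested with an upper-tail hypergeometric test.

## The synthetic generator

`simulate_accessibility()` emulates the structure the analysis assumes: a
random recursive differentiation tree (uniform attachment — branching
concentrates near the root, as in hematopoiesis), a planted tree-respecting
column partition, and per-locus-cluster two-state vectors over the column
clusters. Entries are Bernoulli($\theta_{\text{high}}$) in accessible blocks
and Bernoulli($\theta_{\text{low}}$) otherwise; defaults
$\theta_{\text{low}} = 0.05$, $\theta_{\text{high}} = 0.8$ match the high/low
accessibility fractions seen in real locus clusters. All-zero rows are
redrawn (a master locus is accessible somewhere by construction), and
optional cell-specific rows carry one or two random ones. All randomness
derives from one seed through named substreams, so the tree, states, entries
and motifs are independently reproducible and datasets are bit-identical
across runs.

Two generator design choices guard identifiability and are deliberate:
state vectors are drawn *distinct* across locus clusters (two clusters with
identical accessibility phenotypes are indistinguishable in principle), and
`planted_partition()` can reject planted column clusters smaller than a
floor — recovery studies use ≥ 3 of 30 cell types, since a planted
"cluster" of one cell type carries no block signal.

What the generator does **not** emulate: spatial genome structure, correlated
noise between neighbouring loci, count-valued accessibility, peak-calling
artefacts, or any dependence of motif content on sequence. Recovery results
on synthetic data therefore speak to the algorithms' statistical behaviour
under the assumed block model, not to performance on any particular real
dataset.

## Study sizes and numerical choices

The validation studies in the test suite use: planted-recovery at
$30$ cell types, $k = 5$, $8$ locus clusters × 250 loci, 20 replicates;
optimizer-versus-enumeration on 50 random trees of 6–10 nodes with
$k \in \{2, 3, 4\}$; two-state brute-force comparison over 100 random
mean/weight vectors up to $k = 12$; enrichment calibration over 30
replicates of a 600-locus, 16-cell-type dataset with 25 permutations.
Strict-improvement uses an absolute epsilon of $10^{-9}$; SSE caches agree
with direct scans to $10^{-9}$; two-state tie detection uses $10^{-12}$ on
the split objective. Hierarchical baselines use Ward linkage on Euclidean
distance; k-means baselines use k-means++ seeding with a fixed seed (a tiny
jitter on duplicated centres keeps `stats::kmeans` happy).
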