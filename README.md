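# treecoclust

Tree-constrained co-clustering of binary chromatin-accessibility matrices.

## The problem

Bulk ATAC-seq across a panel of cell types yields, after peak calling, a
binary accessibility matrix **M** (loci × cell types; 1 = locus called
accessible in that cell type). When the cell types sit on a known
differentiation tree — hematopoietic panels are the motivating case — the
question is how the structure of **M** reflects the tree: which loci open and
close together, across which coherent parts of the tree, and how much
cell-type-associated variation a small grid of co-clusters captures.

`treecoclust` implements the full analysis:

* **Matrix construction** from narrowPeak files: 500-bp summit windows, a
  greedy master list of non-overlapping loci (highest-quality window wins its
  overlap group), binary peak–locus intersection, cell-specific locus
  split-off (accessible in ≤ 2 cell types), TSS proximal/distal annotation.
* **Locus clustering**: edges between loci whose shared accessible cell-type
  count is hypergeometrically improbable (upper tail of `P(S ≥ s)` with
  population C, N successes, n draws), thresholded by Benjamini–Hochberg at
  an edge FDR, then Louvain community detection; clusters with ≥ 30 loci go
  downstream.
* **Cell-type clustering under the tree**: the column partition is restricted
  to clusters that *respect* the tree (connected, or all component roots
  children of one parent), encoded as cut vertices with cut groups, and
  fitted by a strictly-improving local search over cut-group / cut-vertex
  moves with 20 random restarts, minimising ‖M − M̃⁽ᵏ⁾‖²_F where M̃⁽ᵏ⁾
  replaces each co-cluster by its mean.
* **Model summaries**: the two-state (inaccessible/accessible) restriction
  M̃ᵢ/ₐ⁽ᵏ⁾ per locus cluster (exact 1-D weighted 2-means), accessibility
  co-clusters, and ANOVA R² decompositions (total and cell-type components).
* **Enrichment**: motif enrichment scores (r − n)/(r + n) over accessibility
  co-clusters with a permutation FDR cutoff; ChIP-seq summit counts per locus
  cluster scaled against a uniform null with hypergeometric association
  tests.
* **Synthetic data**: planted-partition generator (random recursive trees,
  tree-respecting planted column clusters, two-state Bernoulli blocks,
  planted motifs) used throughout the tests.

## Worked example

Simulate a 30-cell-type panel with 8 planted locus clusters and a planted
5-cluster column partition, then run the full recovery analysis:

```r
library(treecoclust)

tree <- random_tree(30, seed = 8)
part <- planted_partition(tree, k = 5, min_cluster_size = 3, seed = 8)
ds   <- simulate_accessibility(n_cells = 30, k = 5, n_locus_clusters = 8,
                               rows_per_cluster = 250, seed = 8,
                               tree = tree, partition = part)

ns  <- split_cell_specific(ds$M, 2)$non_specific
ch  <- choose_edge_fdr(ns)            # operating point: ~70% of loci connected
cl  <- louvain_partition(ch$graph, seed = 0)
big <- restrict_to_large(ds$M, cl, min_size = 30)
run <- optimize_tree_partition(big$M, big$row_labels, tree, k = 5,
                               restarts = 20, seed = 0)
mod <- fit_means(big$M, big$row_labels, run$best_partition)
cocluster_anova(mod)
```

Output:

```
chosen edge FDR: 0.005
similarity_graph: 1955 loci, 36636 edges (p cutoff 9.04e-05); 85.7% connected
locus_clustering: 1955 loci in 299 clusters; largest 263
optimizer_run: k = 5; best SSE 4970.73 over 20 restarts
cocluster_anova over 7 locus clusters:
  overall R2 total     0.5793
  overall R2 cell type 0.997
```

Reading the numbers: the Benjamini–Hochberg cutoff at the chosen edge FDR is
a pairwise p-value of 9×10⁻⁵; Louvain finds the planted locus clusters among
its large communities (the 299 include singletons for unconnected loci); the
tree-constrained search recovers the planted column partition exactly (its
SSE is the planted optimum), the co-cluster grid captures 58% of the total
entry variance — the rest is within-block Bernoulli noise — and 99.7% of the
cell-type-associated variance, which is the component the column clustering
is supposed to explain. `fit_two_state(mod)` then reduces each locus cluster
to an inaccessible/accessible state pair, and `accessibility_coclusters()`
hands the accessible blocks to `permutation_cutoff()` for motif enrichment.

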