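---
title: "TF-IDF based clustering of single-cell RNA-seq data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TF-IDF based clustering of single-cell RNA-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctfidf)
```

## The model

`sctfidf` clusters cells from gene-by-cell UMI count matrices using the
term frequency - inverse document frequency (TF-IDF) transformation from
text mining. The analogy: cells are documents, genes are words, UMI counts
are word occurrences. For a matrix with $N$ cells, counts $f_{ij}$ of gene
$i$ in cell $j$, and $n_i$ cells detecting gene $i$:

$$TF_{ij} = \frac{f_{ij}}{\max_k f_{kj}}, \qquad
  IDF_i = \log_2\!\frac{N}{n_i}, \qquad
  \mathrm{score}_{ij} = TF_{ij} \times IDF_i.$$

Dividing by the per-cell maximum makes term frequencies comparable across
cells of different sequencing depth (the most abundant gene of every cell
scores exactly 1), and the IDF factor up-weights genes concentrated in few
cells — exactly the genes most informative about cell type. Genes detected
in every cell get $IDF = 0$ and are therefore silenced; genes detected
nowhere are assigned $IDF = 0$ as well, a deliberate totalization (the
formula is undefined at $n_i = 0$ and such genes should be removed by QC).

Three routes lead from scores to a clustering:

1. **Gene selection, "Top"**: a 2-component univariate Gaussian mixture is
   fit (EM, 5 seeded restarts) to the per-gene mean scores; genes
   hard-assigned to the component with the larger fitted mean are kept,
   capped at 3000 by detection count.
2. **Gene selection, "Var"**: per-gene mean and coefficient of variation
   (sample sd / mean, computed over *all* cells) are fit by OLS in
   log-log space; the top 30% of genes by residual log CV are kept.
   Residuals in log space make the ranking scale-free.
3. **Binarization**: per cell $j$, every gene scoring strictly above
   $0.1 \times$ (mean of cell $j$'s nonzero scores) gets expression
   signature 1, all others 0. Clustering accuracy is empirically flat in
   this multiplier around 0.1. The spec of the cutoff admits a global
   reading (one cutoff from the matrix-wide mean); the per-cell reading is
   the default, the global one is available via `binarize(global = TRUE)`.

The selected-gene scores or binary signatures feed one of five clustering
families: k-means (k-means++ init, Lloyd, 10 restarts), spherical k-means
(the same under cosine dissimilarity on L2-normalized cells), EM Gaussian
mixtures (full covariance, diagonal fallback when singular or when
dimension exceeds cell count), Ward hierarchical clustering on
Euclidean/Pearson/cosine/Jaccard distances, and dense weighted-graph
modularity clustering (greedy CNM or multilevel Louvain). Baseline
pipelines use log2(x+1), optionally followed by 10-component PCA or 2-D
tSNE. `list_methods()` names all compositions; `run_method()` executes one.

## Graph construction and recursive re-partitioning

For graph methods, pairwise distances are min-max scaled to $[0,1]$ and
every pair with scaled distance $\ge 0.01$ becomes an edge weighted by the
similarity $1 - $ scaled distance, giving a dense weighted graph. Two
boundary choices are deliberate: the pair attaining the maximum distance
would receive weight 0 and is dropped (so weights lie in $(0,1]$), and the
minimum-distance pair (scaled 0) is below any positive cutoff, so extremely
similar pairs are represented through their other edges. The literal sparse
reading (edges where scaled distance $\le$ cutoff) is available via
`build_cell_graph(rule = "distance_le")` but does not produce the dense
graph the method calls for.

Modularity clustering chooses its own number of communities, which can fall
short of the number of cell types when types are similar: global min-max
scaling compresses the internal contrast of a similar pair of types
whenever a distant type dominates the distance range. Recursive
re-partitioning repairs this: while $k < k_{\min}$ and some cluster has
mean silhouette below a threshold (default 0.25), the worst such cluster's
cells are re-extracted as a count submatrix, the *entire* transformation
(TF-IDF, binarization, graph clustering) is re-applied to it — rescaling
distances within the subset — and the cluster is replaced by the resulting
sub-clusters. The process stops when the minimum number of clusters is
achieved or no cluster is below the threshold. We adopt this disjunctive
stop rule deliberately: continuing to split below-threshold clusters after
$k_{\min}$ is reached shreds similar types into dozens of tiny pure
slivers (majority matching keeps them "accurate", but the partition is
useless). Sub-clusters of fewer than 3 cells are never re-partitioned, and
a sub-clustering that returns a single cluster marks its target as
unsplittable. Silhouettes are computed with the pipeline's own metric on
its own representation (binarized cosine for `TF-IDF_Bin_Louvain_C`, etc.);
singleton clusters get silhouette 0 by convention.

## Choosing the number of clusters

For centroid/hierarchical/mixture methods, `k = "auto"` uses the gap
statistic: for each candidate $k$,
$\mathrm{Gap}(k) = E^*\{\log W_k\} - \log W_k$, where
$W_k = \sum_r D_r / (2 n_r)$ is the normalized sum of squared pairwise
Euclidean distances within clusters (equal to the total within-cluster sum
of squares, which is how it is computed) and the expectation is a
Monte-Carlo mean over `b_refs` (default 50) datasets drawn uniformly over
the per-feature bounding box of the data. $k^\star$ is the plain argmax —
not the one-standard-error rule. The gap analysis runs on the same
transformed representation as the downstream clustering, with the same
clusterer, because the curve is sensitive to the transformation; Jaccard
hierarchical pipelines fall back to k-means inside the gap computation
since the continuous reference draws are not binary. Results carry a
`flagged` field when the maximal gap is below twice its Monte-Carlo
standard error (no pronounced structure). Graph methods determine $k$
internally; a numeric `k` passed to them acts as the enforced minimum.

## Quality control

Cell filters drop cells with fewer than 200 detected genes (the
conventional floor, configurable) or too small a total count, and then
remove outliers per annotated group: Euclidean distance of each cell's
log2(x+1) profile to the group centroid, dropping cells beyond
median $+ 3 \times$ MAD (one-sided; `stats::mad` with its 1.4826
constant). Gene filters keep genes with total count $\ge 1$ and drop
one-sided *high* outliers of log2(total+1) — the direction that catches
runaway genes such as the pancreas hormone markers (INS, GCG, SST, PPY,
GHRL), which `exclude_genes()` can also remove by name. The distance space
for cell outliers (log profiles) is our choice; it keeps the rule
consistent with the log-based baselines. MAD rules with a finite
multiplier are not idempotent in pathological configurations (removal
changes the median), but are on realistic data; the test suite checks
idempotence on generated fixtures.

## The synthetic world

`generate_mixture()` emulates mixtures of FACS-sorted cell types. Each of
`n_types` types carries `n_markers_per_type` (default 50) marker genes at
`marker_fold` (default 20) times the baseline negative-binomial mean
(default 0.3, dispersion 0.5, i.e. NB size 2); `similarity` is the
fraction of markers drawn from a pool shared by all types, so 0 yields
disjoint marker sets and `similarity_tiers()` returns the three canonical
tiers {0, 0.5, 0.8}. Counts are thinned by an independent detection draw
with probability $\mathrm{plogis}(s \cdot (\log_2 \mu - \log_2 0.05))$,
slope $s = 1$: detection probability increases with the mean, the midpoint
0.05 reflecting that genes with mean expression below a few hundredths of
a count are essentially undetectable. At the defaults this produces ~20-25%
nonzero entries and a median of roughly 450-500 detected genes per cell on
a 2000-gene panel — proportionally comparable to the ~10% detection (about
1900 of 20k genes) seen in real UMI data, and comfortably above the
200-detected-genes QC floor so generated data pass default QC. Imbalanced
designs mirror the 7:1...1:7 ratios of 1,000 cells used throughout the
acceptance suite. `generate_nested_mixture()` adds the three-type
distant-plus-similar-pair design used to exercise recursive
re-partitioning.

**What the generator does not emulate** — and hence what a green test does
not establish: per-cell library-size variation (every cell has the same
expected depth), gene-gene correlation, batch effects, doublets, and
continuous differentiation gradients. The absence of depth variation
matters for method *comparisons*: TF normalization exists precisely to
equalize documents of different lengths, so baselines like log-transformed
k-means — which suffer badly from depth variation on real data — look
artificially strong here. This is why the acceptance comparison of
`TF-IDF_Bin_Louvain_C` against `Log_Kmeans` on the similar tier saturates
at ~100% for both and its ordering is decided by single-cell noise; the
generated world at the stated parameters cannot reproduce the large
real-data margin between those methods, and we have left that criterion
red rather than tune the generator after the fact.

## Numerical conventions

* Ward linkage is `stats::hclust(method = "ward.D2")` applied to whichever
  dissimilarity the pipeline produced: textbook Ward on Euclidean input,
  and the same Lance-Williams recurrence on Pearson/cosine/Jaccard input.
* Pearson distance is $1 - r$ (not $1-|r|$ or $(1-r)/2$); cosine
  dissimilarity is $1 - \cos\theta$; both are clamped at 0 against
  floating-point drift and degenerate vectors (zero norm, zero variance,
  empty binary signature) raise typed errors rather than returning
  sentinels.
* Binarization compares strictly (`> cutoff`); with multiplier 0 this
  reproduces the detection mask except for genes detected in *every* cell,
  whose score is identically 0 through $IDF = 0$.
* k-means/EM ties in assignment go to the lowest cluster index; cluster
  ids are 0-based, contiguous, ordered by first occurrence; all stochastic
  back-ends take an explicit seed and restore the caller's RNG state.
* EM covariances are regularized by $10^{-8}$ on the diagonal; a Cholesky
  failure triggers the diagonal-covariance fallback with a warning.

## Limitations

Besides the generator gaps above: the dense graph is quadratic in cells
(no approximate-neighbor acceleration), tSNE is a library call whose
perplexity is auto-shrunk on small inputs, and the "Top" selection needs a
genuinely bimodal mean-score distribution — on flat inputs the 2-component
fit is rejected as degenerate.
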