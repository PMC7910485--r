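# snapkit

Peak-free analysis of single-cell ATAC-seq in R: a depth-corrected spectral
embedding of binary cell-by-bin matrices, with landmark (Nyström) scaling,
graph clustering, gene accessibility scores, reference label transfer,
enhancer–gene linkage, and differential accessibility testing. A
synthetic-data module generates ground-truth benchmarks so the whole
pipeline is testable without any external download.

It is aimed at computational biologists analysing sparse single-cell
chromatin accessibility data — especially when peak calling on pooled cells
would bias the feature space against rare populations, or when the dataset
is too large for an all-pairs similarity matrix.

## The method in brief

Cells are binary vectors over fixed-width genomic bins. Their pairwise
similarity is the Jaccard index

> J<sub>ij</sub> = |x<sub>i</sub> ∩ x<sub>j</sub>| / |x<sub>i</sub> ∪ x<sub>j</sub>|,

which is confounded by sequencing depth: for two *unrelated* cells with bin
fractions P<sub>i</sub>, P<sub>j</sub> the expected similarity is

> E<sub>ij</sub> = P<sub>i</sub>P<sub>j</sub> / (P<sub>i</sub> + P<sub>j</sub> − P<sub>i</sub>P<sub>j</sub>),

increasing in either coverage. snapkit fits
J = β₀ + β₁E + β₂E² on a density-balanced subsample of cells, divides it
out (N = J / fit, capped at the 0.99 quantile), symmetric-normalizes
A = D<sup>−1/2</sup> N D<sup>−1/2</sup>, and reports the top-r eigenvectors
as the embedding. Large datasets are handled by eigendecomposing only a
landmark subset and projecting the rest through the landmark eigenbasis
(U<sup>vk</sup> = A<sup>vk</sup> U<sup>kk</sup> / Λ<sup>kk</sup>); an
ensemble of independent landmark samplings is combined as an equal-weight
KNN graph for robust clustering. Downstream: Louvain/Leiden clustering,
Markov-diffused gene-body scores (Ĝ = A<sup>t</sup>G̃), mutual-nearest-
neighbor label transfer with anchor weighting, logistic-regression
enhancer–gene linkage at the 5×10⁻⁸ cutoff with distance-matched negative
controls, and a fixed-dispersion (BCV² = 0.01) negative-binomial exact test
for differential accessibility. The methods vignette
(`vignettes/methods.Rmd`) documents every formula, convention, and default.

## Worked example

```r
library(snapkit)

# ground truth: 4 cell populations over 20,000 genomic bins
profiles <- make_profiles(n_pops = 4, m_bins = 20000, seed = 1)
dataset  <- simulate_cells(profiles, cells_per_pop = 150,
                           coverage_range = c(1000, 10000), seed = 2)
x <- binarize(as_bin_counts(dataset), top_fraction = 0.001)
x
#> cell_bin_matrix: 600 cells x 20000 bins; median coverage 2840.5

# depth-corrected spectral embedding
emb <- embed_matrix(x, r = 10, sample_size = 2000, seed = 1)
round(head(emb$eigenvalues, 5), 4)
#> [1] 1.0000 0.0112 0.0108 0.0105 0.0091

# cluster the KNN graph and compare against the planted populations
labels <- cluster_graph(knn_graph(emb$U, k = 15), seed = 1)
table(labels, truth = dataset$labels)
#>       truth
#> labels   1   2   3   4
#>      0 110   0   0   0
#>      1  40   0   0   0
#>      2   0 149   0   0
#>      3   0   1   0 150
#>      4   0   0 150   0
cat("ARI:", round(ari(labels, dataset$labels), 3),
    " NMI:", round(nmi(labels, dataset$labels), 3), "\n")
#> ARI: 0.928  NMI: 0.943

# the depth confounder, before and after correction
raw <- embed_matrix(x, r = 2, normalize = FALSE)
cat("cor(dim 1, log10 coverage): raw",
    round(cor(raw$U[, 1], log10(x$coverage)), 3),
    "-> corrected", round(cor(emb$U[, 1], log10(x$coverage)), 3), "\n")
#> cor(dim 1, log10 coverage): raw 0.999 -> corrected -0.186
```

Reading the output: the eigenvalue spectrum drops sharply after the four
population dimensions; clustering recovers every population exactly except
population 1, which the cells' ten-fold coverage spread splits into two
pure sub-clusters (ARI 0.93). The last two lines show the point of the
normalization — the leading dimension of a raw Jaccard embedding is
essentially a read-depth axis (correlation 0.999 with log coverage), which
the expected-Jaccard regression removes.

For large datasets, replace `embed_matrix()` with `nystrom_embed(x, k, r)`
(single landmark sampling) or `ensemble_embed(x, p_experts, k, r)` followed
by `cluster_graph()`. A thin command-line front end over the same functions
is installed at `inst/cli/snapkit.R` (subcommands `simulate`, `qc`,
`binmat`, `embed`, `nystrom`, `cluster`, `gscore`, `metrics`).

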