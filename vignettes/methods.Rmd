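---
title: "Methods: depth-corrected spectral embedding of single-cell ATAC-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-corrected spectral embedding of single-cell ATAC-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Single-cell ATAC-seq measures chromatin accessibility in individual cells,
but each cell yields only a few thousand fragments scattered over hundreds of
thousands of candidate regions. Peak-based pipelines call peaks on aggregated
data first, which biases the feature space toward the dominant cell types.
`snapkit` instead works peak-free: the genome is tiled into fixed-width bins
(5 kb by default), each cell becomes a sparse binary vector over those bins,
and all downstream analysis operates on cell-cell similarities of these
vectors.

The central statistical obstacle is sequencing depth. For binary profiles the
natural similarity is the Jaccard index

$$J_{ij} = \frac{|x_i \cap x_j|}{|x_i \cup x_j|},$$

but $J_{ij}$ grows with the coverage of either cell regardless of biology.
The package removes this confounder, embeds cells spectrally, and scales to
large datasets through landmark approximation.

# The model

## Expected Jaccard similarity under the random-cell null

Write $C_i = \sum_k x_{ik}$ for the number of accessible bins of cell $i$ and
$P_i = C_i/m$ for its bin fraction. If two cells are unrelated — their "1"s
placed independently at rates $P_i$ and $P_j$ — the ratio of the expected
intersection to the expected union is

$$E_{ij} = \frac{P_i P_j}{P_i + P_j - P_i P_j}.$$

$E_{ij}$ is increasing in either $P$, which is precisely the depth effect.
The ratio-of-expectations stands in for the expectation of the ratio; the
two agree when the coefficient of variation of both counts is small, i.e.
when $mP$ is not tiny. The Monte-Carlo checks in the test suite therefore
sample $(|A|, |B|, |A \cap B|)$ as Binomial/Hypergeometric sufficient
statistics of Bernoulli vector pairs on a grid with $P \ge 0.05$ at
$m = 10^4$; outside that regime the closed form has a visible Jensen bias
and is not the quantity the method relies on.

## Depth regression and normalization

Real cells are not random, but the dependence of $J$ on $(P_i, P_j)$ is
captured well by regressing observed on expected similarity with a quadratic
correction for the saturation-driven curvature seen among high-coverage
cells:

$$J_{ij} = \beta_0 + \beta_1 E_{ij} + \beta_2 E_{ij}^2 + \varepsilon.$$

The fit is ordinary least squares over all off-diagonal pairs of a subsample
of cells (default 2000) drawn by *inverse-density sampling*: cells are
selected with probability proportional to $1/d(\log_{10} C_i)$, where $d$ is
a Gaussian kernel density estimate (Scott's bandwidth) of the log-coverages.
This over-represents the coverage extremes where the curve must be anchored.
Self-pairs are excluded — the diagonal $J_{ii} = 1$ carries no information
and would bias the intercept.

Normalized similarity divides out the fit,

$$N_{ij} = J_{ij} \big/ (\hat\beta_0 + \hat\beta_1 E_{ij} + \hat\beta_2 E_{ij}^2),$$

with two conventions the formula leaves open:

* **Outlier cap.** Values above the 0.99 quantile of the off-diagonal
  normalized values are set to that quantile. The quantile is computed over
  unique (upper-triangle) pairs so that the matrix path and the
  subsample-fitting path agree exactly.
* **Diagonal.** $N_{ii}$ is set to the maximum off-diagonal value. Leaving
  the raw $1/\mathrm{fit}(1)$ there would let self-similarity dominate every
  row; setting it to the off-diagonal maximum keeps the kernel's scale
  homogeneous. When the cap is active this equals the cap, which also makes
  out-of-sample extension of a duplicated cell land exactly on its original
  row.

A non-positive fitted denominator is treated as an error, not clamped: it
indicates the regression is extrapolating outside the data that fitted it.

## Spectral embedding

With $D_{ii} = \sum_j N_{ij}$, the symmetric graph normalization
$A = D^{-1/2} N D^{-1/2}$ is eigendecomposed, $A = U \Lambda U^T$, and the
first $r$ eigenvectors (descending eigenvalue) form the embedding.
Eigenvector signs are arbitrary, so each column is flipped to make its
largest-magnitude entry positive, giving reproducible output. The first
eigenvector is the Perron direction and is near-constant once depth is
removed; it is kept (the field's plots conventionally index dimensions from
it) and is harmless to clustering.

`select_dimensions()` automates the manual "look for the blob" rule: it
returns the largest $r$ whose eigenvalue gap exceeds twice the mean
consecutive gap, bounded to $[2, 50]$, and accepts a user override. The rule
is deliberately simple; when the leading trivial gap dominates the spectrum
it is conservative, and the pairwise-scatter diagnostic (or an explicit
`override`) is the intended recourse.

# Landmark (Nyström) scaling

The full kernel is quadratic in cell number. The landmark path samples
$k$ cells (inverse-density, so rare coverage strata survive), embeds the
$k \times k$ kernel, and extends the remaining cells:

$$A^{vk} = (D^{vv})^{-1/2}\, N^{vk}\, (D^{kk})^{-1/2}, \qquad
  U^{vk} = A^{vk}\, U^{kk} / \Lambda^{kk},$$

where $N^{vk}$ is the depth-normalized cross similarity, normalized with the
*landmark* regression model and capped at its stored quantile, and
$D^{vv}_{ii} = \sum_j N^{vk}_{ij}$ sums over landmarks only. Eigenvalues
below $10^{-12}$ are excluded from the division (rank guard). Rows are
restored to the original cell order; extension is row-independent, so
batches and single cells give identical results, and the $n \times n$ matrix
is never materialized (peak similarity storage is $O(nk)$).

The ensemble variant repeats this for $p$ experts (expert $j$ reseeded with
`seed + j`), builds a union-symmetrized binary KNN graph from each expert's
embedding, and averages the adjacencies with equal weights $1/p$. Community
detection then consumes the weighted graph. Equal weighting ignores expert
quality but is cheap and already stabilizes clustering markedly; each expert
is symmetrized before combination.

# Downstream machinery

* **Clustering** is an external-algorithm contract: igraph's Louvain
  (default) or Leiden on the exact KNN graph (Euclidean, ties to the lower
  index), deterministic given a seed, labels contiguous from 0.
* **Connectivity index**: for each cell the $K$ nearest neighbors are
  scanned in order and $1/i$ is added when the $i$-th neighbor's label
  differs; reported as the total and the per-cell mean (the total is the
  field's convention; the mean is easier to compare across $n$).
* **Coverage entropy** grids the top-decile-coverage cells on a
  $50 \times 50$ grid spanning the bounding box of the *whole* 2-D
  embedding and reports the Shannon entropy (nats) of the occupancy. The
  box deliberately comes from all cells: a grid fitted to the selected
  subset only measures their internal uniformity and can score a
  depth-confounded embedding as high as a corrected one, hiding exactly the
  concentration the metric exists to expose.
* **Gene scores**: fragments overlapping gene bodies are counted per cell
  (a fragment counts once per overlapped gene), CPM-normalized, and smoothed
  $t = 3$ steps over the row-stochastic KNN adjacency with unit self-loops
  ($\hat G = A^t \tilde G$). Self-loops keep a cell's own signal; smoothing
  is a convex averaging, so scores stay within each gene's observed range.
* **Label transfer**: query cells are projected onto a reference landmark
  embedding by the same extension mechanics, anchored to reference cells by
  mutual 5-nearest-neighborship in the joint space, and each anchor is
  scored by shared-neighbor consistency in a joint 30-NN graph (rescaled
  between the 0.01 and 0.90 quantiles, clipped to $[0,1]$). Each query's 50
  nearest anchors get weights
  $D = (1 - d/d_s)\,S$, softened as $1 - e^{-D/(2/\mathit{sd})^2}$ (the
  constant evaluates to 4 at the default $\mathit{sd} = 1$, implemented
  literally) and row-normalized; label probabilities are $P = WL$ with
  one-hot reference labels. Queries without anchors, or with best
  probability below 0.9, are flagged rather than assigned.
* **Enhancer-gene linkage**: per gene, a logistic regression of each
  nearby peak's binary state on imputed expression; the association is the
  Wald $p$-value of the slope at the genome-wide cutoff $5\times 10^{-8}$.
  Constant peaks are skipped; fits suggesting separation are flagged.
  Negative controls match each positive pair by absolute TSS distance on
  the opposite side of the gene, ties toward the smaller distance. No
  covariates are included — none are defined for pseudo-cells.
* **Differential accessibility**: group counts are aggregated, both vectors
  are rescaled to their geometric-mean library size, and each peak is tested
  with a sum-conditioned negative-binomial exact test at fixed dispersion
  $\mathrm{BCV}^2 = 0.01$. The conditional distribution does not depend on
  the unknown mean (it cancels in the product of NB pmfs), the two-sided
  $p$-value accumulates all splits at most as probable as the observed one,
  and the dispersion-to-zero limit is the binomial exact test. The test is
  implemented in the package (self-contained, enumeration up to the peak's
  conditioned sum); the suite cross-checks it against edgeR's exact test as
  an independent reference. Benjamini-Hochberg FDR at 0.05 flags DARs.

# The synthetic-data generator

`make_profiles()` draws a shared log-normal baseline over bins
(`base_rate = 0.02`, sdlog 0.5) and elevates a disjoint 2% marker set per
population threefold. These defaults were calibrated once so that
between-population profile correlation is about 0.75 — the similarity range
of bulk ATAC profiles of related cell types, which is what downsampled bulk
experiments emulate. Marker bins of other populations are *not* suppressed:
suppression would anti-correlate profiles and make populations unrealistically
easy to separate. The spiked rare population used in the sensitivity
benchmark is the one deliberate exception: it emulates a foreign cell line
(markers at boost 10, profile correlation ≈ 0.35 to the rest), matching the
design of spiking a cultured line into tissue data.

`simulate_cells()` gives each cell a log-uniform target coverage in
1,000-10,000 reads and places reads multinomially under its population
profile — fixed per-cell depth, as in downsampling a bulk library.
`perturb_depth()` thins counts binomially. `render_fragments()` writes a
fragment file whose round trip through the matrix builder is exact (fragments
never cross bin boundaries). `simulate_paired_rna()` creates pseudo-cell
expression (log-normal around a population program) with one true enhancer
peak per linked gene following a logistic model of stated effect size, plus
Bernoulli decoys, and emits the truth table.

What the generator does **not** emulate: batch effects, doublets, Tn5
sequence bias, fragment-length structure, chromosome-scale covariance, or
peak-level dynamics within bins. Passing benchmarks on this data shows the
machinery recovers planted structure under realistic sparsity and depth
confounding — not that any particular biological dataset will reach the same
scores.

# Benchmark problem sizes

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen once: clustering recovery uses 5 populations × 200 cells over 20,000
bins at fixed coverages {10,000, 5,000, 2,000, 1,000} × 3 seeds (medians
reported; each benchmark dataset sits at a single coverage, matching how
downsampling benchmarks are constructed — a single dataset mixing the whole
coverage decade splits populations into pure coverage strata under
modularity clustering, which no resolution setting repairs). Ensemble
stability uses n = 1,500 at 1,000 reads with k = 300 landmarks, 5 experts,
5 runs per arm. The rare-population spike-in uses n = 5,000 with 1% rare
cells and k = 1,000 landmarks. Label transfer uses an 80/20 split of
n = 1,200. Linkage and differential tests use 2,000 pseudo-cells and 1,000
peaks at 10^5 reads per group (5 replicate simulations; empirical FDR is an
expectation and is estimated by pooling replicates).

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED) throughout; overlap means ≥ 1 bp.
* Binarization zeroes the top 0.1% of *non-zero* counts
  (`ceiling(nnz × fraction)`, largest counts first, stable ties) — the
  artifact-trimming denominator is the non-zero entries, which is the set
  the affected alignment artifacts live in.
* Top-coverage bin removal drops `floor(0.05 × m)` columns and is skipped
  when mean per-cell fragment count is below 5,000 (bin ranking is
  noise-driven there).
* Barcode QC: fragment count strictly greater than 1,000; promoter fraction
  within [0.2, 0.8] inclusive.
* Zero-coverage cells, zero kernel row sums, empty graphs, empty gene sets,
  and all-removed bins are errors naming the offending entity; unknown
  chromosomes and pass-list barcodes without fragments are warnings with
  counts.
* Depth-regression degeneracy (constant $E$) falls back to an
  intercept-only model with a warning.
* All samplers take explicit seeds; ensemble experts derive theirs as
  `seed + j`; KNN ties break to the lower index so results are reproducible
  bit-for-bit.

# Known limitations

* The quadratic depth model captures the mean trend of $J$ on $E$ but not
  all coverage structure: on single-population data a residual depth
  direction remains in the trailing eigenvectors even though the leading
  dimension is decorrelated from coverage. This mirrors the method's
  behavior on real data, where small clusters can retain a visible depth
  gradient.
* Modularity-based community detection splits large, internally structured
  clusters (e.g. a population spanning a full coverage decade) regardless
  of resolution; cluster labels are pure but finer than the planted truth.
* The anchor-scoring formula (shared-neighbor fraction with quantile
  rescaling) is one committed interpretation of neighborhood-consistency
  scoring and is isolated behind `score_anchors()` so it can be swapped.
* The expected-Jaccard closed form degrades when $mP$ is small; with very
  few accessible bins per cell the depth regression inherits that bias.
* `fit_landmarks()` eigendecomposes the landmark kernel densely; it is
  intended for $k$ up to a few thousand on one machine. Per-expert
  independence in the ensemble is the natural parallelization seam, but no
  scheduler is shipped.
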