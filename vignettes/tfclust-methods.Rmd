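---
title: "Clustering transcription-factor expression profiles and characterizing the clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering transcription-factor expression profiles and characterizing the clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfclust)
```

## The problem

A bacterial genome encodes hundreds of DNA-binding transcription factors
(TFs), but a large fraction of them are *hypothetical*: predicted by
sequence comparison, never characterized experimentally. When TFs share
expression behaviour across a large compendium of conditions, they tend to
participate in related regulatory programs. `tfclust` implements a
workflow that exploits this: cluster TFs by their condition-contrast
expression profiles, check that the clusters are stable, and then ask
which TF families, regulatory modes and target-gene functional categories
are overrepresented in each cluster. A hypothetical TF inherits a
candidate function from the enriched annotations of the experimentally
characterized TFs it co-clusters with.

The pipeline has four stages, each usable on its own:

1. **Imputation and PCA** of the TF-by-condition log-ratio matrix
   (`impute_missing()`, `fit_pca()`).
2. **Attribute selection**: pick a small set of informative,
   mutually decorrelated conditions (`attribute_projections()`,
   `select_attributes()`).
3. **Spectral clustering** of TFs on a k-nearest-neighbour graph over the
   selected conditions, with the number of clusters chosen from the
   within-sum-of-squares (WSS) curve and stability assessed over random
   restarts (`spectral_cluster()`, `wss_curve()`, `select_k()`,
   `stability_trials()`).
4. **Enrichment**: one-tailed Fisher exact tests with Benjamini–Hochberg
   (BH) correction over TF families, regulatory modes, target-gene
   categories, and overlaps with an external partition (`enrich_*()`,
   `compare_clusterings()`).

`run_pipeline()` chains all four and writes a manifest sufficient to
reproduce the run.

## Attribute selection

Each principal component is a linear combination of all conditions.
For the leading $m$ components we form, per condition $j$, the projection
vector $p_j \in \mathbb{R}^m$ with entries $p_{ji} = \ell_{ji}\,\sigma_i$
(loading times component standard deviation), i.e. the covariance of
condition $j$ with the unit-variance score of component $i$. Selection is
two-step:

* **candidacy** — keep conditions with $\max_i |p_{ji}| \ge \tau_1$
  (default $\tau_1 = 0.15$); conditions that project weakly on every
  retained component carry little of the structure the components
  describe;
* **decorrelation** — visit candidates in descending order of
  $\max_i |p_{ji}|$ (ties by column order) and admit a candidate only if
  the absolute Pearson correlation of its projection vector with every
  already-admitted one is below $\tau_2$ (default $0.9$). Blocks of
  near-duplicated conditions — ubiquitous in compendia, where many
  contrasts probe the same perturbation — thus contribute one
  representative each, the most informative one.

Both thresholds are exposed because the candidacy cut is a judgment call;
a threshold that is too low admits noise conditions, one too high leaves
too few attributes to cluster on. $m$ defaults to the smallest component
count reaching a cumulative explained-variance goal (default 0.65) and can
be fixed directly. Two practical caveats, both visible in the tests: the
Pearson correlation of two $m$-vectors is degenerate ($\pm 1$) for
$m = 2$, so decorrelation needs $m \ge 3$ to be meaningful; and the
candidacy threshold separates signal from noise only when noise is spread
over many conditions (each noise condition then loads weakly on any single
component), which is the compendium regime. A projection vector with zero
variance cannot witness a correlated block; its correlation is defined
as 0.

## The estimator

`spectral_cluster(x, k)` performs normalized spectral clustering:

* **Graph**: directed 3-nearest-neighbour lists under the Euclidean
  metric, symmetrized by union ("weak"; an edge if either endpoint lists
  the other) or intersection ("mutual"). Ties in neighbour ranking break
  by row order. Weights are binary by default; Gaussian weights
  $w_{ij} = \exp(-d_{ij}^2 / 2\sigma^2)$ are available.
* **Laplacian**: unnormalized $L = D - A$, weighted $L_W = D - W$,
  random-walk $I - D^{-1}W$, or (default) the symmetric normalized
  $L_{NS} = D^{-1/2}(D - W)D^{-1/2}$. Normalized variants reject isolated
  nodes. Random-walk eigenvectors are computed from the symmetric variant
  via $u = D^{-1/2}v$, which shares its eigenvalues.
* **Embedding**: the eigenvectors of the $k$ smallest eigenvalues. The
  trivial first eigenvector is included by default and rows are
  normalized to unit length for the symmetric variant (the standard
  normalized-cut recipe); `include_trivial = FALSE` drops it and takes
  the next $k$, since both conventions appear in practice.
* **Assignment**: k-means on the embedding, best of 25 restarts,
  convergence when assignments stabilize or after 300 iterations.

**The polish step.** Cluster quality is reported as within/between/total
sums of squares (WSS/BSS/TSS) in the *original* selected-attribute space,
because that is the space practitioners interpret. By default the spectral
labels additionally seed one Lloyd k-means pass in that space, so the
reported labels are a local optimum of the very objective they are scored
by; boundary points snap to the nearest cluster centroid. On the planted
benchmark below this lifts label recovery to the level of a
nearest-true-centroid assignment, which is the information ceiling once
missingness has destroyed the discriminating coordinates of some rows.
`polish = FALSE` gives the classical embedding-only assignment. The polish
is kept only if it preserves all $k$ clusters.

WSS + BSS = TSS holds exactly (law of total variance), and the suite
asserts it on every fit.

## Choosing the number of clusters

`wss_curve()` refits the whole embedding-and-assignment per candidate $k$
and records total WSS. The descent at $k$ is
$\Delta(k) = \mathrm{WSS}(k{-}1) - \mathrm{WSS}(k)$. A descent is *major*
when it exceeds the robust outlier bound
$\mathrm{median}(\Delta) + c\cdot\mathrm{MAD}(\Delta)$ (default $c = 2$);
consecutive major descents form a run, and `select_k()` reports each run
by its terminal $k$ — the last cluster count whose gain is still
outlier-large, i.e. where the descent completes and the curve flattens.
This formalization was chosen after observing that $\Delta$ typically
decreases *monotonically* through the true $k$ before collapsing (the
gain of splitting one merged pair of planted clusters at $k$ is smaller
than the gain at $k-1$, which also unmerged a pair), so the true $k$ is
the end of the outlier run, not a local maximum of $\Delta$. A smooth
decay with no outlier descent selects nothing, with a warning. The rule
is deterministic given the curve and reports multiple structure scales
(e.g. a coarse and a refined clustering) as separate run ends.

`stability_trials()` repeats the assignment stage with `n_trials`
different initialization streams on a fixed graph and embedding and
reports the coefficient of variation of total WSS (percent) and the mean
pairwise adjusted Rand index (ARI) of the label vectors. Each trial keeps
the best of its own restarts, so the report measures the spread of
converged solutions rather than of raw initializations; a well-separated
solution yields CV near 0 and pairwise ARI near 1.

## Enrichment

All tests are one-tailed Fisher exact tests: the upper-tail
hypergeometric probability $P(X \ge a)$ with margins fixed, summed in log
space (log-binomial coefficients combined by log-sum-exp) so large tables
stay accurate. BH correction is applied within each analysis family
(one scheme, the family analysis, the mode analysis, one partition
comparison), and significance is called at adjusted $p <$ 0.045.

Counting units differ by analysis and matter for interpretation:

* **categories** — genes; a cluster's gene set is the union of the
  targets of its *experimentally characterized* (strong/weak evidence)
  TFs, each gene counted once per cluster. The universe defaults to the
  union of all clusters' target genes; `"all_annotated"` (every gene of
  the scheme) is offered because p-values depend strongly on this choice.
* **families** — TFs, among all clustered TFs with a family annotation.
* **regulatory modes** — (TF, gene, mode) interactions, since the same
  gene can be activated by one TF and repressed by another.
* **partition comparison** — TFs, or target-gene sets after expanding
  each cluster through its TFs' regulons.

A caution the tests make explicit: under label permutation the gene-level
category test is overdispersed, because a TF's whole regulon moves
between clusters as a block. Isolated borderline hits can therefore
survive permutation even though the planted signature pattern never does.
This unit-of-analysis effect is inherent to gene-level set tests, not an
implementation artifact. Note also that the BH step-up adjustment is not
an idempotent map on p-values (re-adjusting adjusted values can raise
tied values below the maximum); the tests assert the true monotonicity
properties instead.

## The synthetic benchmark

`synthetic_spec()` defines the study conditions used throughout the
validation: 120 TFs in 4 planted clusters over 10 informative conditions,
20 pure-noise conditions and 3 duplicate blocks (3 near-copies each,
jitter sd = noise sd/100, so within-block correlations exceed 0.9 by
construction), centroid separation 6 in units of the within-cluster noise
sd, and 5% of entries masked uniformly at random. Centroids sit on scaled
coordinate axes of the informative subspace, so every pair of centroids is
exactly `separation` apart and difficulty is a single interpretable knob;
a consequence worth knowing is that `noise_sd` is a pure scale parameter —
doubling it rescales the data without changing the clustering problem.
The column counts were fixed once at values representative of a small
compendium slice: enough noise conditions that selection has something to
reject, few enough that a 20-seed ensemble runs in seconds.

`generate_annotations()` plants one signature category, one
overrepresented family and one biased regulatory mode per cluster
(signature carry probability 0.8 against a 0.05 background; family and
mode bias 0.7), with evidence classes sampled at 40/25/35%
strong/weak/hypothetical to mimic a realistically mixed catalog — only
strong/weak TFs contribute targets, as for real regulons.

What passing these benchmarks shows — and does not. The generator is
Gaussian, axis-aligned, with uniform missingness and non-overlapping
regulons. Real compendia have heavy-tailed noise, correlated missingness,
heavily overlapping regulons and annotation bias toward well-studied
genes. Planted-truth recovery therefore validates the machinery
(graph, spectra, sums of squares, test statistics and their calibration),
not the biological accuracy of any particular clustering of real data.

At these conditions about 5% of rows lose their discriminating
coordinate to masking and become genuinely ambiguous; even assignment to
the nearest *true* centroid mislabels them. That ceiling is ARI ≥ 0.9 in
roughly 90% of seeds, and the polished estimator tracks it.

## Numerical and degenerate-input choices

* Loadings are sign-fixed (largest-magnitude coordinate positive) so
  results do not depend on the eigen-solver's arbitrary signs.
* Symmetric eigenproblems only; the random-walk case is transformed, not
  solved nonsymmetrically.
* k-means empty clusters: retried with fresh starts, an error only if
  persistent; `k = n` and `k = 1` short-circuit to exact answers.
* Duplicate points in the graph are allowed; neighbour ties break by row
  order, documented and deterministic.
* Validation rejects rather than repairs: duplicate identifiers,
  unknown regulatory modes or evidence classes, and non-numeric cells are
  hard errors naming the offender. A row that is entirely missing cannot
  be row-mean imputed and errors by name.
* All randomness flows from explicit seeds; the pipeline fans a master
  seed out to fixed per-stage offsets so changing the trial count does
  not perturb earlier stages.

## Reference fixtures

The package ships a transcription of the published 12-cluster assignment
of the 291 *E. coli* K-12 TFs (`reference_clusters()`): per-cluster sizes
and WSS, and the membership list with evidence classes and synonyms.
Transcription defects in the source table are flagged rather than
guessed: one unnamed entry, two entries lost to extraction (placeholder
rows keep the published sizes authoritative), one TF listed twice. The
fixture supports the arithmetic checks (sizes summing to 291; 1807
regulated genes of 4679 = 38.6%) and gives users a concrete partition to
compare their own clusterings against with `compare_clusterings()`.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run the full pipeline on the
120 × 33 benchmark over 20 generator seeds, the type-I calibration over
50 seeds, stability over 100 trials, and oracle comparisons on graphs up
to n = 50 and tables up to n = 40 — sizes chosen so the whole suite
completes in well under a minute while keeping every ensemble estimate's
sampling error far from its acceptance margin. Reproducing the published
12-cluster analysis requires the original 291 × 303 supplementary
expression matrix, which is third-party data not redistributed here; the
final test in `test-acceptance.R` documents where to place it and runs
the complete reproduction when present.

## Limitations

* PCA is linear; clusters defined by correlation-shaped (non-radial)
  similarity may be split or merged before the graph ever sees them.
* The dense eigendecomposition is O(n³); fine for hundreds of TFs, not
  for tens of thousands of genes.
* Enrichment treats categories as flat labels; no hierarchy-aware
  (GO-style) correction is attempted.
* The universe choice changes gene-level p-values substantially; both
  options are explicit rather than hidden.
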