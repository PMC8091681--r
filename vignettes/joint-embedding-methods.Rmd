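---
title: "Joint embeddings of multimodal single-cell data: models and choices"
author: "jembed maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint embeddings of multimodal single-cell data: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Technologies such as CITE-seq and SNARE-seq measure several molecular
layers — mRNA, surface proteins (ADT), chromatin accessibility — in the
same cells. t-SNE and UMAP visualize one layer at a time, and cell
populations that coincide in one layer but differ in another are rendered
indistinguishable. `jembed` implements j-SNE and j-UMAP, which embed all
layers into a single two-dimensional map while *learning how informative
each layer is*.

## Model

For modality $k$ let $P^{(k)}$ be the usual perplexity-calibrated,
symmetrized Gaussian affinity over cells computed on that modality's
processed view, and let $Q$ be the Student-t affinity of a shared
embedding $Y$. j-SNE minimizes

$$C(Y, \alpha) \;=\; \sum_k \alpha_k\, \mathrm{KL}\!\left(P^{(k)} \,\|\, Q\right)
\;+\; \lambda \sum_k \alpha_k \log \alpha_k,
\qquad \alpha \ge 0,\; \textstyle\sum_k \alpha_k = 1 .$$

The weights $\alpha$ are the importance of each modality; the negative
entropy term with regularization parameter $\lambda \ge 0$ pulls them
toward uniform. j-UMAP is the analogous generalization of UMAP: per
modality, a fuzzy $k$-NN membership graph $V^{(k)}$, and a convex
combination of fuzzy cross entropies instead of KL divergences.

Optimization alternates two exact steps:

1. **Embedding step (α fixed).** Because every KL term shares the same
   $Q$, $\sum_k \alpha_k \mathrm{KL}(P^{(k)}\|Q)$ equals, up to a constant
   in $Y$, the plain t-SNE objective on the aggregated affinity
   $\bar P = \sum_k \alpha_k P^{(k)}$. The embedding step is therefore
   conventional t-SNE gradient descent on $\bar P$ (and conventional
   UMAP edge-sampling SGD on $\bar V = \sum_k \alpha_k V^{(k)}$, where
   the attractive force on an edge is proportional to its combined
   membership).
2. **Weight step (Y fixed).** Minimizing
   $\sum_k \alpha_k L_k + \lambda \sum_k \alpha_k \log \alpha_k$ over the
   simplex has the closed form $\alpha_k \propto e^{-L_k/\lambda}$ — a
   Gibbs distribution over modality losses. At $\lambda = 0$ the analytic
   limit is one-hot on the smallest loss (the single most informative
   modality; first index on ties); large $\lambda$ forces uniform
   weights. Since the update is the exact minimizer, the total objective
   can never increase across a weight step — asserted per iteration in
   the tests.

The loop stops when the largest weight change falls below `alphaTol`
(default $10^{-3}$) or after `maxOuterIter` (default 10) outer
iterations. Defaults $\lambda = 3$ for j-SNE and $\lambda = 1$ for
j-UMAP are used everywhere.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lambdaReg` | 3 (j-SNE) / 1 (j-UMAP) | entropy pull toward uniform weights; smaller values down-weight noisy modalities more aggressively |
| `perplexity` | 30 | effective neighbor count of the Gaussian conditionals (t-SNE branch) |
| `nNeighbors` | 15 | fuzzy graph neighborhood size (UMAP branch) |
| `maxOuterIter` | 10 | alternating iterations |
| `alphaTol` | 1e-3 | convergence threshold on max weight change |
| `innerItersFirst` / `innerItersLater` | 500 / 100 | t-SNE gradient steps in the first / later outer iterations |
| `nEpochs` / `nEpochsLater` | 500 / 100 | UMAP SGD epochs in the first / later outer iterations |
| `minDist`, `spread` | 0.1, 1.0 | UMAP layout kernel, fitted to $(1 + a d^{2b})^{-1}$ |

The standard preprocessing is library-size scaling to the median
total count, $\log(1+x)$, then PCA to 20 (or 50) components; PCA is
skipped for modalities with fewer features than the requested number of
components (small antibody panels). No feature selection or batch
correction is performed.

## Design choices where the design was genuinely open

* **Warm starting.** Only the first outer iteration runs a full
  embedding schedule (early exaggeration for t-SNE, full-rate SGD for
  UMAP). Later outer iterations continue from the current layout:
  100 gradient steps without exaggeration (t-SNE), or 100 SGD epochs at
  an initial learning rate annealed as $0.5/(t-1)^2$ (UMAP). The
  annealing is what lets the layout and the weights settle jointly;
  with a constant continuation rate the weight trajectory keeps
  wobbling a few times $10^{-3}$ per iteration and never meets
  `alphaTol`.
* **Per-modality cross entropy for the weight step.** Conventional UMAP
  never evaluates its loss, so j-UMAP needs an explicit estimator. The
  stored-edge part is summed exactly; the non-edge part
  $-\log(1-w_{ij})$ is estimated from a seeded uniform sample of
  non-edge pairs drawn once per run outside the *union* of all
  modalities' edge sets and reused for every modality and outer
  iteration — so differences between modality losses are never sampling
  noise. Union pairs that are not edges of a given modality are summed
  exactly for that modality. The total is normalized by
  $n \cdot \texttt{nNeighbors}$, which brings it to the $O(1)$ scale of
  a (normalized) KL divergence so that $\lambda = 1$ is a meaningful
  default at the cell counts this package targets (hundreds to a few
  thousand).
* **Neighbor search.** Exact brute-force $k$-NN at every size. All
  study sizes here are at most a few thousand cells, where exactness is
  cheap and makes results bit-reproducible.
* **Embedding initialization.** t-SNE branch: seeded Gaussian
  ($\sigma = 10^{-4}$), with PCA initialization available. UMAP branch:
  spectral layout of $\bar V$ (deterministic dense eigendecomposition,
  used up to 2048 cells when the graph is connected), otherwise seeded
  Gaussian.
* **Ties and degenerate input.** KNI breaks distance ties toward the
  lower cell index; `updateWeights` at $\lambda = 0$ picks the first
  minimizer; $0 \log 0 = 0$ throughout; $q_{ij}$ is floored at
  $10^{-12}$ inside logarithms; kernel values in the cross entropy are
  clipped to $[10^{-12}, 1 - 10^{-12}]$; cells with all-zero counts are
  an explicit error.

## The synthetic data generator

`simulateMultimodal()` draws grouped RNA and ADT counts from a
Splatter-style hierarchical gamma–Poisson model: feature means
$\sim \Gamma(0.6, \text{rate } 0.3)$, expression outliers (probability
0.05, log-normal factor around 4 times the median mean), per-group
multiplicative DE factors $\sim \mathrm{LogNormal}(0, 1)$ on a random
feature subset (inverted with probability 1/2), log-normal library sizes
(log-mean 9.5 for RNA, 7.0 for ADT), negative-binomial counts via
gamma–Poisson (dispersion 0.2 RNA / 0.4 ADT) and logistic dropout on the
log mean (strong for RNA, negligible for ADT). The DE probability is
0.1 for genes and 0.5 for antibodies: ADT panels are curated marker
panels, so most antibodies separate cell types — which also makes ADT
the most informative modality in the simulation, consistent with how
the weight-learning behavior is exercised here. These values are
documented stand-ins chosen to produce sparse, overdispersed,
CITE-seq-like counts; they are not estimates from any real dataset.

`makeShuffledModality()` builds the noise modality: a copy of a count
matrix in which the expression vectors of a random subset of cells
(fraction $f$) are permuted among themselves. `toyConfoundedScenario()`
builds the two-modality toy: four equal groups of 10-dimensional
Gaussian blobs (unit noise, separation 6) where modality A collapses
groups 1 and 2 onto one center and modality B collapses groups 3 and 4.
The named presets `N1k`, `N5k`, `N5kD1k` (1k/5k cells, 2000 or 1000
genes) are this package's own reconstructions of a 1k/5k-cell design.

What the generator does *not* emulate: batch effects, expression
paths/trajectories, mean–variance trends beyond a constant dispersion,
ambient contamination, or doublets. Passing tests therefore demonstrate
the optimization behaves as designed under a clean hierarchical NB
model, not that it is robust to every artifact of real data.

## Study conditions used by the tests and the acceptance script

* Toy confounded scenario: $n = 200$, seeds 0–4 (tests) or three seeds
  derived from `--seed` (script).
* Noise sweep: $n = 1000$ cells, 5 groups, modalities RNA + ADT +
  shuffled-RNA, shuffle fractions $\{0, 0.2, 0.4, 0.8, 1\}$, five seeds
  (tests; the script uses fractions $\{0, 0.4, 0.8\}$ and two seeds).
* Baselines: fixed uniform weights ($\alpha_k = 1/K$, `fixedWeights`)
  and conventional t-SNE/UMAP on the feature-wise concatenation of count
  matrices, each optionally divided by its Frobenius norm, followed by
  PCA to 20 components.
* Numerical checks: the weight update against a $10^{-3}$ simplex grid;
  the embedding gradient against central finite differences on 15-point
  instances; the sampled cross entropy against the exact $O(n^2)$
  evaluation at $n = 100$.

## Known limitations

* On the toy scenario, joint j-UMAP decisively improves neighborhood
  purity (KNI) over both unimodal maps, but its mean silhouette stays
  slightly below the unimodal ones: UMAP membership strengths are
  locally calibrated, so the confounding modality contributes
  cross-pair edges at near-within-group strength, and the SGD
  equilibrium leaves the two resolved-but-adjacent clusters of a
  confounded pair close together. Independent layout engines run on the
  identical combined graph reach the same equilibrium, so this is a
  property of the graph-combination objective at these conditions, not
  of this implementation. j-SNE, whose affinities are globally
  normalized, improves both metrics.
* Exact $O(n^2)$ affinities and gradients bound practical problem sizes
  to a few thousand cells; tree- or interpolation-accelerated gradients
  are out of scope.
* Cross-entropy magnitudes grow with cell count faster than normalized
  KL terms; the $n \cdot \texttt{nNeighbors}$ normalization keeps
  $\lambda = 1$ sensible at the targeted sizes but has not been
  examined beyond ~5000 cells.
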