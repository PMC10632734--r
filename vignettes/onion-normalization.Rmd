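---
title: "Onion normalization of gene fitness matrices: methods and design"
author: "onionnet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Onion normalization of gene fitness matrices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onionnet)
```

## The problem

Genome-wide CRISPR knockout screens across cell-line panels yield a gene
x cell-line matrix of fitness effects (CERES/Chronos-style scores).
Correlating gene profiles across cell lines produces a co-essentiality
network in which strongly correlated genes tend to share function — a
cheap, genome-scale proxy for protein-complex and pathway membership.
In practice the strongest low-dimensional structure of such matrices is
not specific biology: a small number of dominant components, heavily
loaded on mitochondria-associated genes, saturate the top of the
correlation ranking and mask signal for most other complexes.

`onionnet` removes that dominant structure in three interchangeable
ways, and then integrates the results across hyperparameter settings:

1. **PCA normalization.** Fit PCA with genes as variables (centered and
   scaled), reconstruct the matrix from the first `n` components,
   `W L_n L_n^T`, and keep the residual. The residual lives in the
   standardized coordinate system; Pearson correlations downstream are
   invariant to per-gene affine maps, so un-scaling is not needed.
2. **Robust PCA (principal component pursuit).** Decompose `X = L + S`
   by minimizing `||L||_* + lambda ||S||_1`; the low-rank part `L`
   absorbs dominant structure and the sparse part `S` — the normalized
   layer — keeps specific dependencies. `lambda = f / sqrt(max(r, c))`.
3. **Autoencoder normalization.** Train a 1D convolutional autoencoder
   on preprocessed gene profiles for one epoch, and subtract the
   decoder's reconstruction from the preprocessed matrix.

Each method has one effective hyperparameter (`n`, `f`, latent size
`LS`) with no universally correct value. **Onion normalization**
sidesteps the choice: normalize at every grid value (`n = 1, 3, ..., 19`;
`f = 0.7, ..., 1.3`; `LS = 1, 2, 3, 4, 5, 10`), turn each layer into a
Pearson similarity network, convert to distances (`1 - r`), apply a
scaled exponential kernel, and fuse the resulting affinity stack with
similarity network fusion (SNF). The fused network (PCO / RPCO / AEO by
method) is the deliverable. For AEO the similarity network of the
un-normalized data is fused as a seventh layer.

## Algorithmic choices

**Principal component pursuit.** The solver is the augmented-Lagrange
iteration: singular-value thresholding on `L` (threshold `1/mu`),
elementwise soft-thresholding on `S` (threshold `lambda/mu`), dual update
`Y <- Y + mu (X - L - S)`, at constant penalty
`mu = r c / (4 ||X||_1)`, stopping when the relative Frobenius residual
falls below `1e-7` (cap 5000 iterations). We keep `mu` constant rather
than growing it: a geometric `mu` schedule reaches feasibility but
collapses the singular-value threshold before the sparse component
forms, losing optimality — on planted rank-2-plus-spikes data it returns
a rank-50+ `L` with ~0.5 relative error, while the constant schedule
recovers the planted factors to `1e-7`. A thin LAPACK SVD is used at
every iteration; at the matrix sizes this package targets a partial SVD
buys nothing.

**lambda and the rank of `L`.** Larger `f` makes sparsity more
expensive, so the low-rank component absorbs more dimensions (measured:
rank 8 at `f = 0.7` versus 16 at `f = 1.3` on a random matrix); the
grid therefore spans reconstructions from conservative to aggressive.

**Affinity kernel.** `affinityNetwork()` reproduces the SNF convention
exactly: local scale `eps_ij = (mu_i + mu_j + d_ij) / 3` with `mu_i` the
mean distance of `i` to its `k` nearest neighbours (self excluded), and
weight equal to the Gaussian *density* of `d_ij` at sd `sigma * eps_ij`
— including the normalizing prefactor. The scale is floored at machine
epsilon for coincident points; neighbour ties resolve by node order. A
5-node hand-evaluated oracle pins the implementation in the tests.

**SNF.** `snfFuse()` implements cross-diffusion with the published
normalization conventions: full kernels are row-normalized with the
1/2-diagonal rule (off-diagonal mass 1/2, diagonal 1/2), sparse kernels
are row-normalized over the `k` nearest neighbours, each round updates
`P_v <- S_v %*% mean(P_-v) %*% t(S_v)` followed by symmetrization and
re-normalization, and the output is the symmetrized, re-normalized mean.
Defaults follow the settings used for dependency-map networks:
`sigma = 0.3, k = 5` for PCO, `sigma = 0.5, k = 5` for RPCO/AEO, 10
iterations. A literal loop-based reference implementation is the test
oracle on small cases.

**Autoencoder.** Encoder: conv(1→10, k3, pad 1) → maxpool(2) →
conv(10→20, k3, pad 1) → maxpool(2) → flatten → linear(→LS); decoder
mirrors it with max-unpooling (consuming the encoder's pooling indices),
transposed convolutions — which at stride 1, padding 1 are themselves
length-preserving convolutions, and are parameterized as such — and a
final linear layer restoring the profile length. The architecture
specifies no elementwise activation, and by default none is used (max
pooling/unpooling is the nonlinearity); ReLU after each convolution is
available via `AeConfig(activation = "relu")` and both variants pass the
finite-difference gradient checks. Training is minibatch Adam on mean
squared reconstruction error, 1 epoch by default. Because desk-scale
matrices provide only tens of minibatches per epoch, the defaults are
`learningRate = 0.01`, `batchSize = 32`; with the more conventional
`lr = 1e-3, batch = 64` a 1-epoch run on ~1,000 profiles stays at its
random initialization. The residual is formed in the preprocessed value
space (the space the reconstruction lives in). Runs are bit-reproducible
under a fixed `AeConfig` seed (weight init and shuffling use an isolated
RNG scope).

**Benchmarking.** Pairs are labeled against a complex standard:
positives share a complex, negatives lie in the standard's universe
without sharing one, and pairs whose two members are both on the
exclusion list are removed from the evaluation entirely (pairs with one
excluded member are kept). Ranking is by descending weight with
lexicographic pair-id tie-break. The PR output reports precision against
the absolute TP count (recall is also emitted). Per-complex AUPRC
restricts the ranking to co-complex pairs — the focal complex's pairs are
positives, all other complexes' pairs negatives — and scores by
step-interpolated average precision. In diversity breakdowns, a TP pair
annotated to `m` complexes contributes `1/m` to each, so fractions sum
to one; the top 10 complexes by overall contribution are named and the
rest aggregate to `"other"`. All benchmark outputs are invariant to
strictly increasing transforms of the weights.

**kNN tissue classifier.** Leave-one-out over cell lines; neighbours are
the `K` most similar other lines (weight ties by id order); majority
vote with voting ties resolved by the single most similar neighbour's
label. Overall precision/recall/F1 are support-weighted means; classes
never predicted contribute precision 0. The random baseline redraws
every label uniformly from the observed label multiset, 100 times.

## What the synthetic generator emulates

`generateSynthetic()` builds a gene x cell-line matrix as the sum of

- a **low-rank confounder** whose gene loadings are confined to a
  designated "mito-like" gene set (15% of genes by default), scaled so
  its leading singular value is `confounderStrength` (default 3) times
  the strongest complex signal — the analogue of the dominant
  mitochondria-associated component, and the generator asserts
  post-generation that it is the top singular direction;
- **complex co-essentiality**: each planted complex's genes share one
  latent cell-line factor (25 disjoint complexes of 3–12 genes by
  default; a configurable fraction of them lives inside the confounder
  set, as mitochondrial complexes do);
- **tissue structure**: each tissue's cell lines share elevated
  dependency on a small disjoint set of lineage marker genes (2% of
  genes per tissue). This is deliberately a sparse block rather than a
  dense per-tissue factor: a dense factor is itself low-rank structure
  and would be removed by RPCA by construction, whereas lineage signal
  in real dependency maps manifests through specific marker-gene
  dependencies;
- i.i.d. Gaussian noise (sd 1) and a uniform missingness mask (2%),
  independent of the values.

Default sizes (800 genes x 120 cell lines) keep a full RPCO run around
a minute on one CPU while leaving PR curves stable. Two experiment
scenarios are fixed once and reused by the tests and the acceptance
script: the **AE confounder experiment** (1,200 x 64, rank-1 confounder
at strength 6, noise 0.3 — a regime with one dominant component and
enough profiles that a 1-epoch run trains), and the **lineage
experiment** (`confounderStrength = 8, tissueEffect = 1.5` — a heavily
confounded raw cell-line network, the regime in which normalization
visibly rescues tissue-of-origin prediction; raw weighted F1 sits near
0.2 and RPCO roughly doubles it).

What passing these tests does **not** show: the generator makes no
attempt to match real dependency-map marginals, screen-quality
artifacts, copy-number effects, or overlapping complex structure beyond
an opt-in flag; conclusions about real data rest on full-scale
dependency-map analyses, not on these synthetic checks.

## Numerical and degenerate-input policies

- Imputation is gene-wise mean substitution; a fully missing gene
  profile is an error. Observed entries are preserved bit-for-bit.
- `aePreprocess()` refuses constant profiles (sd 0); clipping at |z| = 4
  precedes the global min-max map to `[-1, 1]`.
- `pccNetwork()` drops zero-variance profiles with a warning and errors
  if more than 10% of nodes would be dropped.
- Edge rankings, neighbour selections and k-nearest sets all break ties
  deterministically (weight, then lexicographic id), so `topEdges(N1)`
  is a prefix of `topEdges(N2)` for `N1 <= N2` and repeated runs are
  identical.
- The RPCA solver and SNF are deterministic; the autoencoder and the
  synthetic generator are deterministic given their seeds.
- Fusing layers with differing node sets falls back to the intersection
  with a warning, and errors if the intersection covers less than half
  the union.

## Known limitations

- The autoencoder is a from-scratch implementation tuned for
  desk-scale profile lengths (tens to hundreds of conditions); it is not
  a GPU-scale training harness.
- `rpcaDecompose()` solves the noiseless principal component pursuit
  program; there is no stable-PCP noise term — Gaussian noise ends up
  distributed between `L` and `S` as the optimum dictates.
- Per-complex AUPRC follows the convention of ranking only co-complex
  pairs; complexes with no scored pair are omitted (with a warning)
  rather than imputed.
- The expression pathway (MTX → filters → log-normalization → RPCA →
  max-weight fusion) is provided end to end but is exercised at toy
  scale in the tests.
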