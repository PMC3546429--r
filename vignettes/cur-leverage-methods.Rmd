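---
title: "CUR decompositions by statistical leverage: models, choices, limits"
author: "leverageCUR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CUR decompositions by statistical leverage: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leverageCUR)
```

## The model

A CUR decomposition approximates an m × n data matrix A by the product
C U R, where C collects c actual columns of A, R collects r actual
rows, and U = C⁺ A R⁺ links them (C⁺ is the Moore–Penrose
pseudoinverse). Unlike the SVD, whose singular vectors mix all
features, the factors are data elements a practitioner can look up —
for an expression matrix, genes and samples. The price is optimality:
for a fixed reconstruction rank s the SVD truncation is the best
possible approximation (Eckart–Young), and any CUR of the same rank
has at least that error. The package treats that bound as a built-in
diagnostic: `approximationError()` reports ‖A − CUR‖_F/‖A‖_F, and the
test suite checks the bound on every strategy.

Which columns and rows enter C and R is decided by the **normalized
statistical leverage scores** at a rank parameter k,

$$\pi_j = \frac{1}{k}\sum_{\xi=1}^{k} v_{j\xi}^2,$$

with v¹,…,v^k the top-k right singular vectors (left vectors for row
scores — mathematically the same as running the column computation on
Aᵀ, which is why no second SVD is performed). Up to the 1/k factor
these are the diagonal entries of the hat matrix, the orthogonal
projector onto the top-k singular subspace; they sum to one per axis
and lie in [0, 1/k]. The choice of k is consequential: leverage at
k = 1 finds features aligned with the single dominant direction, while
larger k spreads attention across the subspace. k should come from
domain knowledge (e.g. the number of sample classes minus one, when
class contrasts are what the analysis is after).

## Tunable parameters

* **k** (rank parameter, positive integer ≤ min(m, n)). If omitted,
  `defaultRank()` picks the smallest k whose top-k singular values sum
  to *strictly more than* 80% of the total singular-value sum. Two
  details are deliberate: the rule uses the singular values themselves
  (not their squares, which would reach 80% much earlier), and the
  inequality is strict. The threshold is exposed
  (`defaultRank(d, threshold)`), default 0.80. On a spectrum
  50, 30, 15, 5 the cumulative shares are 50%, 80%, 95%: the rule
  returns 3, because 80% is not strictly more than 80%.
* **c, r** (selection sizes, positive integers). Fixed input sizes;
  the package does not derive them from an error target. For the
  `random` strategy c and r are expectations, not guarantees. Setting
  `r = "all"` switches to the restricted one-sided form (below).
* **method** — one of `random`, `exact.num.random`, `top.scores`,
  `ortho.top.scores`, `highest.ranks` (accepted verbatim).
* **seed** — consumed only by the two randomized strategies; it is
  applied through an internal scope that restores the caller's RNG
  state, so package calls never perturb a user's random stream.

## The five selection strategies

`random` is the classical importance sampler: keep index j with
probability p_j = min{1, c·π_j}, independently. Only the expected
count equals Σp_j. An empty draw (possible for small c) is redrawn
from the running stream up to 100 times before erroring — silent empty
output would break every downstream step.

`exact.num.random` keeps the importance weighting but guarantees the
output size: weighted sampling *without* replacement of exactly
`count` indices with weights min(1, count·π_j) (via R's sequential
weighted sampler). The weighting mechanism is this package's
concretization; the defining property is the exact count.

`top.scores` ranks by score, descending, ties broken by ascending
index. Fully deterministic, and the recommended strategy when the
selection itself is the scientific result (a gene list should not
change between runs).

`ortho.top.scores` addresses correlated features: after each pick the
remaining candidates are rescored by
π_j · ‖(I − P_S)a_j‖₂/‖a_j‖₂, the leverage score damped by the
fraction of the candidate's vector lying outside the span of the
already-selected set (P_S is the orthogonal projector onto that span,
maintained as a Gram–Schmidt basis). A duplicate of an already-chosen
column scores zero and is skipped, so near-redundant selections are
avoided. Only a qualitative description of this strategy exists in the
CUR literature this package follows; the multiplicative
leverage-times-residual form used here was chosen because it reduces
exactly to `top.scores` when the data are orthogonal, and zeroes out
exact duplicates. If every remaining candidate falls (numerically,
relative tolerance 1e-10) inside the selected span before `count` is
reached, the remaining slots are filled by raw leverage score and the
result carries `spanFilled = TRUE` rather than failing.

`highest.ranks` tries every rank parameter k′ = 1..k, ranks the
features by leverage at each k′ (rank 1 = highest, ties by ascending
index), and gives each feature its best rank attained anywhere as its
merit. Features that dominate the spectrum at *some* rank — perhaps
only at k′ = 1 — are favoured. Ties in merit are resolved by the rank
at k′ = k, then by index. The best-rank merit and this tie cascade are
likewise this package's concretization of a two-sentence description.

All tie-breaks throughout the package are by ascending index, so every
deterministic strategy is a pure function of its inputs.

## Restricted (one-sided) decomposition

When only interpretable *columns* are wanted, r = "all" skips row
selection and the approximation becomes the projection of A onto the
span of C: A ≈ P_C A = C X with X = C⁺A. The object stores U = C⁺
only; `getX(object, A)` performs the product on demand. This keeps the
stored object small (X is c × n) and mirrors how the decomposition is
used: X is a set of regression coefficients that is often never needed
explicitly.

## Numerical choices

* **Sign convention.** In each right singular vector the entry of
  largest absolute value is made non-negative (ties at the lowest
  index), with the paired left vector flipped too. Leverage scores are
  sign-invariant, but selections and PCA scores become bit-stable
  across runs and platforms. The same convention fixes PCA score signs
  via the loadings.
* **Pseudoinverse tolerance.** `pinv()` zeroes singular values below
  max(dim)·ε·σ_max (ε = machine epsilon), the standard cutoff. This
  matters in practice: a C factor containing highly correlated columns
  is numerically rank-deficient, and inverting its trailing singular
  values would amplify noise instead of linking the factors.
* **Error norm.** "Approximation error" is the relative Frobenius
  norm ‖A − CUR‖_F/‖A‖_F, the norm in which the CUR theory's
  guarantees are stated; the absolute norm is recoverable by
  multiplying with ‖A‖_F. A zero input matrix has no relative error
  and is rejected.
* **Rank-deficient leverage.** For k beyond the numerical rank
  (σ_k < 1e-12·σ_1) the singular vectors span an arbitrary basis of
  the null space; `leverageScores()` still computes (the scores remain
  a valid probability vector) but warns, because the result depends on
  that arbitrary basis.
* **Median convention.** The separation statistic uses R's default
  median: the midpoint of the central order statistics for even
  counts.
* **PCA conventions.** `pcaScores()` centers features and does not
  scale by default — the usual convention for log-expression data,
  where variance carries signal; scaling is available but refuses
  zero-variance features. Sample scores are computed on the transposed
  (samples × features) matrix via `stats::prcomp`.

## The separation statistic

For every unordered pair of groups, all cross-group Euclidean
distances between sample coordinates are computed and summarized by
their median; the statistic is the sum over group pairs. It is
translation- and rotation-invariant and scales linearly with the
coordinates — which cuts both ways. Within one embedding it cleanly
quantifies how far groups sit apart, robustly to outlying samples. But
it is *not* dimensionless: embeddings with different overall scales
(e.g. PCA scores from 27 genes versus 5520 genes) produce values on
different scales, so `separationSweep()` emits the all-features
baseline row explicitly instead of normalizing by it, and ratios
across very different feature counts should be read with that caveat
in mind.

## What the generators emulate — and what they do not

`generateLowRank()` produces signal = (m × rank Gaussian) × (rank × n
Gaussian), optional additive Gaussian noise, and optionally
`nPlanted` columns built to be orthogonal to the signal span, mutually
orthogonal, and scaled to the mean signal column norm. Each planted
column then owns a singular direction, so at k = rank + nPlanted its
leverage approaches the 1/k maximum and `top.scores` must recover it —
the ground truth behind the recovery tests. Defaults (60 × 40, rank 4,
noise sd 0.1) match the scale at which the package's property tests
operate.

`generateGroupedExpression()` emulates the geometry of a
soft-tissue-tumor microarray study: 5520 features × 31 samples in
three phenotype groups (sizes 11/10/10; only the total is fixed by the
study geometry), with 27 group-informative features by default.
Informative feature i is assigned a group round-robin and shifted by
`effect` in that group's samples, mean-centered across samples, so the
shift structure spans (number of groups − 1) dimensions and leverage
at k = G − 1 concentrates on the informative features once `effect`
exceeds `noiseSd`. The defaults effect = 2, noiseSd = 1 were fixed
once as a realistic strong-differential-expression regime (a 2-unit
shift on log-scale data with unit residual sd).

Two features of real expression data are deliberately *not* emulated.
First, real studies carry pervasive correlated structure — batch
effects, co-expression modules — whereas the generator's background is
independent noise; in real data the class signal is also visible in
the all-gene PCA, while here the all-gene PCA of a 5520-feature
matrix is noise-dominated and the reduced-to-full separation ratio
sits well below one even though the reduced set is the one that
discriminates. Passing tests therefore demonstrate recovery of
*planted sparse* structure, not performance on correlated designs.
Second, expression values are not Gaussian; leverage scores only see
second-order structure, so this mainly affects how realistic the noise
tails are, not the algebra under test.

## Problem sizes and test design

The property suite runs on matrices between 5 × 5 and 60 × 40 (100
seeded instances for the normalization, bound and hat-matrix-oracle
properties; 50 for exact recovery and the Eckart–Young bound across
all five strategies), 1000 seeded draws for the exact-count contract,
200 seeds for the Bernoulli count aggregate, a 2¹⁰-outcome exact
enumeration as the oracle for the count distribution, and 20 generator
seeds for planted-column recall at noise sd 0 and at 10% of the signal
scale. These sizes were chosen so each property is exercised across
shapes while the whole suite stays comfortably interactive. Oracles
are kept independent of the paths they check: the Gram-matrix
eigendecomposition for singular values and leverage, `MASS::ginv` for
the pseudoinverse, QR projectors for the restricted form, and explicit
double loops for the separation statistic.

## Known limitations

* Dense matrices only, held in memory; no sparse storage or
  randomized/sketched SVD. The intended scale is the
  thousands-of-features × dozens-to-hundreds-of-samples regime.
* Selected columns are returned as-is; no 1/√(c·p_j) rescaling is
  applied to C or R. Rescaling would tighten some theoretical
  guarantees but destroys the interpretability that motivates CUR —
  the factors would no longer be actual data columns.
* `ortho.top.scores` and `highest.ranks` are greedy heuristics; no
  optimality claims are made beyond the reductions and recovery
  properties stated above.
* The sweep's separation values inherit the scale-dependence discussed
  above; they are comparable within an embedding dimension, not across
  arbitrary feature-set sizes.
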