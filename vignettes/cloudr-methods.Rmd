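---
title: "Methods: OU simulation, features, and the regularized network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OU simulation, features, and the regularized network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its model, its defaults, and the
design decisions taken where the design was genuinely open. Nothing here
reports an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The evolutionary model

A duplication in species 1 produces a parent copy P (at the ancestral locus)
and a child copy C; the sister species 2 retains the single-copy ortholog A,
a proxy for the pre-duplication state. Expression in each tissue evolves
along the three-gene tree as an Ornstein–Uhlenbeck process: Brownian drift
of rate σ² pulled toward an optimum θ with strength α. Time is rescaled so
the gene-tree root has height 1; the duplication sits at scaled time
`t_PC ∈ (0, 1)`. The optima before duplication equal the ancestral optimum
(θ_PC = θ_PCA = θA), so each tissue's triplet (eP, eC, eA) is trivariate
normal with the closed-form mean and covariance implemented in `ouMean()`
and `ouCovariance()`. Two readings fixed at implementation time:

* The printed form of the covariance lists the bottom-right entry as the
  child's variance twice; the only self-consistent reading is Var[eA], which
  is what `ouCovariance()` returns (the matrix is exchangeable in P and C
  anyway).
* All optima, expression values and background summaries live on the log10
  expression scale throughout; natural-scale statements of the parameter
  ranges (θ up to 10⁴, α ∈ [1, 10³], σ² ∈ [10⁻², 10³]) are read as the
  log-scale ranges θ ∈ [−4, 4], log10 α ∈ [0, 3], log10 σ² ∈ [−2, 3].

Tissues are assumed independent — the covariance structure is per-tissue
only. This is a modelling assumption, not a limitation of the code path, but
no intertissue covariance extension is implemented.

## Retention classes as constraints on the optima

`drawScenarios()` samples per-tissue parameters under one of five constraint
sets: Conserved (θP = θC = θA), NeofunctionalizedParent (θC = θA, θP free),
NeofunctionalizedChild (θP = θA, θC free), Subfunctionalized
(θP + θC = θA exactly, built by construction as θC = θA − θP), and
Specialized (all three free with θP ≠ θA, θC ≠ θA, θP + θC ≠ θA).
Equality constraints are exact; "not equal" constraints are enforced by
rejection sampling at tolerance 10⁻⁶ — equality is a measure-zero event for
continuous draws, but class identity must be decidable and testable, so the
tolerance guarantees a minimum separation without imposing any minimum
effect size. Note that the subfunctionalization sum constraint applies on
the drawing scale, so θC can leave [−4, 4] (its range is [−8, 8] after the
subtraction); this is inherent to building the additive constraint exactly.

α is drawn log-uniformly over three decades and σ² over five; both are
wide enough that the hardest corner (weak selection, strong drift) is close
to unclassifiable and the easiest corner (strong selection, weak drift) is
nearly deterministic. The scaled duplication time is shared by all tissues
of a duplicate. When gene trees are available their `t_PC` estimates form
the sampling pool; otherwise `t_PC ~ Uniform(0.05, 0.95)`, a broad fixture
default that avoids the degenerate ends where the duplication coincides
with either the present or the speciation.

## The single-copy background

All rank and moment features compare a duplicate against the genome-wide
divergence of single-copy genes. With the two-species tree scaled to root
height 1 and divergence at the root, Brownian motion makes the two species'
expression values iid Normal(θ, σ²) per tissue, so the maximum-likelihood
fit is the closed form θ̂ = (s1+s2)/2, σ̂² = (s1−s2)²/4 (`fitBmTwoTip()`) —
no comparative-methods machinery is needed for a two-tip tree, and the
closed form is unit-tested directly. Simulation draws (θ, σ²) pairs jointly
from the fit pool (preserving any θ–σ² dependence; whether to sample jointly
or independently was open, and joint sampling is the more faithful reading
of resampling "from the estimated empirical distribution"), then draws both
species iid normal. When no empirical single-copy table is supplied, the
fit pool is synthesized with θ ~ Uniform[−1, 3] and σ² log-uniform on
[10⁻², 1] — a broad, plausible log10-FPKM-like background; the standard
background size is 10,000 genes. A gene whose expression vector is constant
in either species has no defined Pearson correlation; its correlation is
recorded as 0 (no linear relationship) with a warning, the same policy the
feature module applies to degenerate triplets.

## The feature vector

Each duplicate becomes `p = 4m+84` features in a fixed, versioned order:
the scaled duplication time; the raw 3m triplet; the per-tissue parent+child
sums; four Euclidean distances (P–C, P–A, C–A, and (P+C)–A); three
three-point branch lengths; four ranks among dist(G); 8 moments × 4 distance
comparisons normalized by max dist(G); four Pearson correlations; four ranks
among cor(G); and 8 moments × 4 correlation comparisons (no normalizer — the
differences are already O(1)). Decisions taken where the layout was open:

* **Raw, not central, moments** of the difference distribution: the first
  central moment is identically zero, which would destroy the location
  information the feature exists to carry.
* **Rank convention**: 1-based, counting strictly smaller pool elements;
  ties take the lower rank. Ranks are stored unnormalized (1 to |G|+1); the
  network's feature standardization absorbs the scale.
* **Negative branch lengths** (three-point condition failures) pass through
  unmodified — they are features for the classifier, not tree estimates.
* **Moments via power sums**: the kth raw moment of (v − pool)/c expands
  binomially over precomputed pool power sums, making the per-observation
  cost independent of the 10,000-gene pool; the pool is normalized before
  the power sums are taken so no large intermediates arise, and the
  expansion is validated against the direct sum in the tests.

## The network and its training

The classifier and predictor share one dense feed-forward architecture:
L ∈ {0..3} hidden ReLU layers of widths 256/2^(ℓ−1), a softmax head with
categorical cross-entropy (classification, K = 5) or a linear head with the
per-observation residual sum of squares over K = 5m outputs (prediction).
The cost adds an elastic-net penalty λ Σ [(1−γ)w² + γ|w|] over all weights;
biases are never penalized. Training is minibatch Adam (learning rate 10⁻³,
β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸, batch 5,000, 500 epochs), Glorot-uniform
initialization, deterministic given the seed. Choices made where the
notation or the description was open:

* **Biases are per-unit**, matching standard dense-layer practice and the
  mainstream framework implementations of this architecture; a literal
  one-scalar-bias-per-layer mode is available via
  `networkConfig(scalarBiasPerLayer = TRUE)`.
* **Feature standardization is on by default**: rank features span
  [1, 10⁴+1] while moment features are O(1), and penalized gradient training
  is scale-sensitive. The z-scoring statistics come from the training set,
  are stored in the model, and are re-applied at scoring. Whether the
  original pipeline standardized its inputs is unknowable from its
  description; this is the single choice to which headline classification
  accuracy is most sensitive, and `networkConfig(standardize = FALSE)`
  exposes the literal raw-feature pipeline.
* **Prediction targets**: α and σ² are regressed on the log10 scale — the
  scale on which the training draws are uniform — and the linear head can
  extrapolate beyond the training range.
* **Arithmetic** is single precision in the compiled training core (the
  fp32 convention of mainstream deep-learning backends), with subnormal
  floats flushed to zero: Adam's second-moment accumulators for vanished
  gradients otherwise fall into subnormal territory and stall SSE
  arithmetic. All surrounding numerics are double precision.
* **Argmax ties** break toward the lowest class index (documented, tested).
* Validation loss in cross-validation is the **mean per-observation
  unpenalized loss** on the held-out fold (cross-entropy, or RSS summed
  over the K outputs). For the balanced 50,000-observation design the
  stratified folds are 40,000/10,000 with 8,000/2,000 per class.

With L = 0 the classifier reduces to multinomial regression; the test suite
cross-checks this reduction against an independent multinomial fit.

## Problem sizes

The full-size study is: 10,000-gene background, 50,000 training
observations (10,000 per class), 5,000 test observations, 500 training
epochs. The package runs the headline classification experiment at exactly
this size. Cross-validation experiments are run at the package's standard
CV problem size of 20,000 observations (16,000/4,000 stratified folds,
3,200/800 per class) in the acceptance script, and at 10,000 observations
in the test suite; mixed-mechanism robustness scenarios use 200 replicates
per scenario. Every experiment entry point takes a `scale` argument that
multiplies all per-class counts proportionally.

## What the synthetic generator does and does not emulate

The generator reproduces the study conditions exactly: stationary OU
triplets with tissue independence, class-constrained optima, log-uniform
selection and drift, one expression draw per parameter draw, and a
Brownian-motion single-copy background. It does not emulate: intertissue
expression covariance, measurement noise beyond the OU stationary variance,
non-stationarity at the root, missing tissues, quantile-normalization
artefacts, or the skewed empirical distribution of gene-tree duplication
times (the fixture uses a uniform `t_PC`). Tests passing on simulated data
therefore demonstrate correctness of the method under its own model, not
classification accuracy on any particular empirical system — tailoring to
real data happens through `runEmpiricalPipeline()`, which rebuilds the
background, fit pool and duplication-time pool from the user's data before
training.

## Degenerate inputs and numerical tolerances

* `t_PC` estimates from degenerate trees (zero-length duplication branches,
  duplication at the root) are clamped into [10⁻³, 1−10⁻³] with a warning.
* Unrooted three-taxon gene trees carry no root position; the root is
  placed on the ancestor's pendant branch so that the ancestor's
  root-to-tip path equals the mean parent/child root-to-tip path, which
  recovers the original root exactly for ultrametric trees. Rooted input
  trees must already isolate the ancestor at the root; a strict-ultrametric
  mode errors on non-ultrametric input instead of averaging path lengths.
* The trivariate sampler uses the analytic Cholesky factor of the
  structured OU correlation matrix, with square-root arguments clamped at
  zero against roundoff; it is verified against the closed-form moments by
  Monte Carlo in the tests.
* Constant expression vectors yield Pearson correlation 0 with a warning,
  both in the background and in the feature module.
* Cross-entropy evaluation clips probabilities at 10⁻¹².

## Known limitations

* Tissue independence is assumed everywhere; expression covariance across
  tissues (shared regulation) is not modelled.
* Exactly three genes: no outgroup or fourth taxon, so the Specialized
  class is identified only through the training constraints, not through an
  over-parameterized likelihood.
* Regularization is elastic-net only: no dropout, early stopping, or
  ensembling.
* The per-observation information about σ² (and, to a lesser degree, α and
  the optima under weak selection) is intrinsically thin — a single
  stationary draw per tissue — so parameter predictions in the
  weak-selection/strong-drift corner are imprecise for any estimator, and
  per-observation regression losses have a large irreducible floor.
* CPU only; the network is desk-scale by design.
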