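---
title: "Decoding gene-gene associations from autoencoder weights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding gene-gene associations from autoencoder weights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedecode)
```

## The model

`aedecode` treats a trained autoencoder not as a black-box compressor but as
a container of learned gene-gene structure. One model is trained per
phenotype class of a cohort (for example chemosensitive vs chemoresistant,
or good vs poor prognosis by a survival median split). Each model is a
single-hidden-layer feedforward network whose input and output layers both
have one node per gene. A sample's expression vector $g \in \mathbb{R}^I$ is
encoded and reconstructed as

$$h = f(W^{enc} g + b^{enc}), \qquad \hat g = f(W^{dec} h + b^{dec}),$$

with $f$ one of six activations (linear = identity, ELU, ReLU, PReLU,
sigmoid, tanh). Training minimizes the reconstruction loss

$$\mathrm{MSE} = \frac{1}{K} \sum_{k=1}^{K} \sum_{i=1}^{I}
  (\hat g_{i,k} - g_{i,k})^2,$$

a mean over the $K$ samples but a *sum* over the $I$ genes. The asymmetry is
deliberate and preserved everywhere: reported losses scale with the gene
count, and the per-sample statistic used for classification is the inner sum
alone.

### Weight decoding

The package's central operation converts trained weights into a signed
association score between every ordered gene pair. Every path from input
gene $i$ through hidden node $h$ to output gene $o$ carries the product of
its two weights, and the score accumulates all paths:

$$S_{o,i} = \sum_{h} w^{dec}_{o,h}\, w^{enc}_{h,i},$$

the matrix product $W^{dec} W^{enc}$. Biases are excluded. For a linear
model with zero biases, $S$ is exactly the network's input-to-output
Jacobian: perturbing gene $i$ by $\delta$ moves the reconstruction of gene
$o$ by $S_{o,i}\,\delta$, which is what justifies reading $S_{o,i}$ as the
signed predictive effect of $i$ on $o$. A converged linear autoencoder with
hidden size $k$ implements (up to parameterization) the projection onto the
top-$k$ principal subspace of the training data, so large $|S_{o,i}|$
off-diagonal entries mark gene pairs that co-load on dominant covariance
directions, with the sign of the product of their loadings.

The top $K$ pairs by $|S|$ (default 200, each direction counted separately,
self-pairs excluded) become a directed network. Edge sign is the score
sign; pairs selected in both directions are flagged mutual. Hubs are genes
appearing in at least `hub_min_degree` (default 2) selected pairs, and
modules are the connected components of the undirected projection, each
labeled by its highest-degree gene. Connected components are a declared
interpretation — the network-construction idea underdetermines the module
rule — and the component labels make module identity deterministic.

### Classification by reconstruction error

With one model per class, a sample is assigned to the class whose model
reconstructs it with the smallest summed squared residual. The contrast
carrying the signal is covariance structure: a class model spends its hidden
capacity on its own class's dominant factors, so samples expressing the
other class's factors reconstruct poorly. Exact ties (possible only in
degenerate hand-built models) resolve to the lexicographically first class
label, with a warning.

### Hidden-node enrichment

Each hidden node induces a gene ranking by its encoder weights (signed, by
default; ties broken by gene identifier). Preranked gene-set enrichment on
that ranking uses the weighted Kolmogorov–Smirnov running sum: hits advance
by $|m|^p / \sum_{hits} |m|^p$, misses retreat by $1/(N - N_{hit})$, and the
enrichment score (ES) is the signed extremum. The null distribution comes
from random placements of the set's genes in the list (gene-label
permutation — the only admissible null for a preranked list). NES divides
the ES by the mean magnitude of same-sign null scores; the nominal p-value
is the smoothed same-sign tail frequency $(k+1)/(n+1)$; the FDR q-value is
the ratio of null to observed tail fractions of pooled NES values within
sign, clipped to $[0, 1]$. Reporting conventionally filters at $|NES| > 1.5$
and $q < 0.05$, but the unfiltered table is always written.

## Parameters and defaults

* `hidden_size` — no universal default; choose against the expected latent
  rank. For decoding planted or suspected co-expression factors, one hidden
  node per factor concentrates $S$ on real structure; excess nodes spend
  capacity on sampling-noise directions and dilute the top pairs. For
  reconstruction-error classification the opposite holds: giving every
  class model enough capacity to span the *whole* cohort's factor structure
  makes the label-permutation null behave as a null (both models can
  represent everything, so nothing systematic separates them), while the
  true-label contrast survives because capacity is allocated to each class's
  own factors first.
* `activation` — `linear` is the default throughout the package's own
  protocols: it matches the spectral analysis above, decodes to an exact
  Jacobian, and in practice performs comparably to the nonlinear choices on
  expression matrices. PReLU carries one learnable slope per layer,
  initialized at 0.25.
* Optimizer — minibatch Adam, learning rate $10^{-3}$, batch 32. The
  training objective fixes only the loss; Adam is chosen for robust
  convergence across all six activations without per-activation tuning.
  Batch size and learning rate are exposed; small dense problems converge
  fastest full-batch at $10^{-2}$.
* Early stopping — training stops when the best loss has not improved by at
  least `min_delta` ($10^{-6}$) for `patience` (100) consecutive epochs, or
  at `max_epochs` (10,000). When epoch checkpoints are requested (for
  misclassification-vs-epoch curves) early stopping is disabled so every
  checkpoint is reached.
* Initialization — every weight *and bias* is drawn from
  $N(0,\, 2/\mathrm{fan\_in})$ with fan-in read as the receiving layer's
  input count (encoder: gene count; decoder: hidden size). Biases are
  included in the draw deliberately; zeroed biases would change nothing
  structural but the Gaussian draw keeps the contract uniform.
* Normalization — per-gene z-score with *population* (1/n) variance, so
  every row has exactly unit second moment; a rank-based inverse-normal
  transform (`qnorm((rank - 0.5)/n)`) is available for heavy-tailed inputs.
  Z-scoring is the default because it preserves the linear covariance
  structure a linear autoencoder represents. Zero-variance genes are set to
  all zeros rather than dropped so gene indices stay aligned across
  per-class matrices. Normalization is applied to the full cohort before
  splitting (a documented switch of the pipeline's `normalize` field; apply
  `normalize_genes()` to the per-class matrices yourself for the other
  order).
* Survival split — samples at or above the cohort median of DRFS days are
  `good`, below are `poor`; a sample exactly at the median survives at
  least the cutoff, hence `good`.
* GSEA — weight exponent $p = 1$ (the standard weighted statistic), 1,000
  permutations, set-size filter $[15, 500]$ after intersection, all
  configurable.

## Numerical choices and degenerate inputs

* Top-$K$ ties are broken by $(|S|$ desc, source id asc, target id asc$)$;
  selection is fully deterministic.
* The ES extremum on an exact tie between the positive and negative
  deviation resolves to the positive one. Such ties are analytically
  possible (e.g. a singleton set placed symmetrically) and float rounding
  would otherwise make the sign depend on metric scaling.
* A gene set intersecting all ranked genes has an undefined miss penalty
  and is an error, as is an empty intersection. If every hit metric is
  exactly zero the hit increments fall back to uniform steps.
* Non-finite training loss aborts with a diagnostic pointing at the
  learning rate.
* All randomness (initialization, epoch shuffling, fold assignment,
  permutation null, cohort simulation) is governed by explicit integer
  seeds, restored on exit, so identical configuration and seed reproduce
  results bit-for-bit under single-threaded BLAS; the pipeline manifest
  records every parameter and seed of a run.

## The synthetic cohort generator

`synthetic_spec()` / `generate_cohort()` produce the two-class cohorts used
throughout the test suite: within a class, each sample is
$\sum_f \lambda_f z_f + \varepsilon$ with $\pm 1$ loadings on disjoint gene
blocks, standard-normal factor scores and $N(0, \sigma^2)$ noise, then
z-scored per gene. Within-block correlation is analytically
$1/(1+\sigma^2)$, and the planted covariance eigenstructure is known, which
is what lets the test suite compare trained losses to the principal-subspace
optimum $\sum_{j>k} \lambda_j$ and decoded top pairs to known signed ground
truth. DRFS days are exponential with class-specific means (defaults 2,000
vs 800) so the survival median split recovers the classes at a known error
rate.

The reference conditions are 40 genes, 500 samples per class, two disjoint
5-gene factors per class on class-disjoint blocks, loading magnitude 1 with
sign pattern $(+,+,+,-,-)$, and noise sd 0.1. What the generator does *not*
emulate: probe-level noise, batch effects, heavy-tailed expression,
correlated noise, or overlapping pathway structure. Passing the recovery and
classification checks on these cohorts therefore demonstrates that the
machinery is correct — that decoding returns planted structure when the
model assumptions hold — not that real cohorts, where factors overlap and
noise is structured, will decode as cleanly.

## Problem sizes in the checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
full battery completes in minutes on one core: oracle equivalence on 100
random models of at most 10 genes and 5 hidden nodes; spectral-optimum
training on 20 genes x 300 samples; recovery on the 40-gene reference
cohort trained 2,000 epochs with 2 hidden nodes (one per planted factor);
classification with 200 training and 100 test samples per class at 4 hidden
nodes (the full planted rank, per the capacity argument above);
determinism on 20-gene, 40-sample-per-class runs of 60 epochs. The
misclassification figures quoted in the README are whatever those runs
print — they are recomputed, not stored.

## Known limitations

* Decoding interprets $S$ as a Jacobian, which is exact only for linear
  activations with the bias-free reading; for nonlinear models $S$ ignores
  the activation derivatives at the operating point and is a first-order
  heuristic.
* One hidden layer only. The path-sum decoding extends to deeper stacks as
  a product of weight matrices, but nothing in the package builds or trains
  them.
* The permutation FDR pools null NES across sets of different sizes; with
  very few sets the q-values are coarse.
* Kaplan–Meier curves and proportional-hazards testing of predicted groups
  are deliberately out of scope; the prediction tables are written so any
  survival toolkit can consume them.
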