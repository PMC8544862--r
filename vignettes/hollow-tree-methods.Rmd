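---
title: "Directional feature importance for boosted trees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional feature importance for boosted trees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hollowtree)
```

## The problem

Tree ensembles predict well but explain poorly. The classical importance
summaries each miss something: impurity-based (Gini) importance ranks
features but says nothing about direction; permutation importance likewise;
partial dependence is directional but limited to one or two features per
plot, which does not scale to the hundreds or thousands of features typical
of, say, connectome-wide neuroimaging tables. This package implements a
pipeline that produces *signed, magnitude-comparable, per-class* feature
importances for gradient boosted binary classifiers, together with the three
baseline methods for comparison.

## Per-prediction path decomposition

The building block is the additive decomposition of a single prediction.
For a decision tree, every node stores the expected model output of the
training samples routed through it (the class-1 fraction for a probability
tree). Following a sample $x$ from the root to its leaf, each split tests
one feature and moves the expectation from the parent's value to the chosen
child's. Crediting each increment to the feature tested gives

$$f(x) = \mathrm{bias} + \sum_{k=1}^{K} \mathrm{contribution}(x, k),$$

where the bias is the root's expectation and $\mathrm{contribution}(x,k)$
sums the (child $-$ parent) increments of all splits on feature $k$ along
the path. The sum telescopes, so the identity is exact — the package treats
it as an invariant and the test suite checks it to $10^{-9}$ on every model
it builds ("conservation"). Repeated splits on one feature accumulate on
that feature; features absent from the path contribute exactly zero.
Contributions may be negative even for the class finally predicted; nothing
is clipped, because the aggregation stage handles directional semantics.

For a boosted ensemble the same walk is done in every tree and summed in
log-odds (margin) space, where tree outputs are additive: the bias becomes
the base score plus the per-tree root expectations, and
$\mathrm{bias} + \sum_k \mathrm{contribution}(x,k)$ equals the total margin,
whose logistic transform is the predicted probability. Internal nodes of
boosted trees do not natively carry an expectation, so the trainer (and the
model-dump importer) reconstructs it as the cover-weighted mean of each
node's descendant leaves, cover being the number of training samples routed
through the node.

## The aggregation pipeline

Per-prediction decompositions become a global, per-class importance in six
steps, run inside stratified $k$-fold cross-validation (default $k = 5$):

1. **Decompose** every held-out prediction of the fold's boosted model into
   per-feature log-odds contributions.
2. **Orient** each decomposition to its predicted class: for samples
   predicted negative, contributions are negated, turning them into log odds
   of the predicted class.
3. **Filter**: drop incorrect predictions and those whose confidence
   $\max(p, 1-p)$ is below the threshold (default 0.7). The boundary case is
   kept: only strictly less confident predictions are dropped.
4. **Aggregate**: within each class partition, sum contributions per feature
   and divide by the number of retained predictions in that partition,
   giving an average weight per prediction. The denominator is deliberately
   the retained count, not the sample count, because the average is defined
   over the predictions that survive filtering.
5. **Sign**: for each feature compute
   $s = \mathrm{sign}(\bar{x}_{y=1} - \bar{x}_{y=0})$ from the fold's
   held-out samples; multiply positive-class weights by $s$ and
   negative-class weights by $-s$. A positive signed weight then means
   "larger values of this feature push toward this class". The class means
   are taken on the held-out split so the step stays out-of-sample and is
   well defined per fold; $s = 0$ (exactly equal means) zeroes the weight
   with a warning rather than guessing a direction.
6. **Average across folds** and count, per feature, the folds in which it
   carries a nonzero weight (magnitude above `appearance_epsilon`,
   default $10^{-12}$) in either class. Sporadic-but-strong features are
   exactly the ones this pair of outputs is designed to expose: a low fold
   count with a large weight.

By default the cross-fold mean divides by $k$, counting folds where a
feature is absent as zero, so magnitudes remain comparable across features;
`fold_average = "present_folds"` divides by the appearance count instead,
for users who want the conditional average. Which convention published
iris-scale analyses used is not recoverable from their reported numbers, so
both are provided and the magnitude-comparable one is the default.

A consequence of the pipeline's algebra worth knowing: relabeling the
outcome ($y \to 1-y$) negates every gradient and therefore every raw
contribution, the orientation step negates them back, and the sign step's
$s$ flips — so the positive and negative signed weight vectors *swap
exactly*, without an additional sign flip. Empirically the two vectors are
close to mirror images of each other anyway, which can make the swap look
like a flip; the exact invariant is the swap, and the suite asserts it.

## Trainers

Both trainers are exact, greedy and fully deterministic, which makes every
pipeline result reproducible from a fold assignment alone.

* `cart_tree()` grows a probability-space tree (default depth 4) minimizing
  weighted binary Gini impurity $2p(1-p)$ over all midpoints between
  consecutive distinct feature values; `x <= threshold` routes left; gain
  ties resolve to the lowest feature index, then the lowest threshold.
* `boosted_trees()` is Newton boosting with logistic loss: leaf weight
  $-G/(H+\lambda)$ scaled by the learning rate, split gain
  $\tfrac12[G_L^2/(H_L+\lambda) + G_R^2/(H_R+\lambda) - G^2/(H+\lambda)]$.
  Defaults are 100 trees, learning rate 0.3, depth 6, $\lambda = 1$, base
  score 0 (log odds), mirroring common boosted-tree practice; the analyses
  this package emulates do not pin hyperparameters, so these are package
  choices, not reproductions.

Externally trained boosters are supported through the common JSON dump
dialect (`nodeid` / `split` / `split_condition` / `yes` / `no` / `leaf` /
`cover`). Cover statistics are required, because internal expectations are
reconstructed from them. Two numeric subtleties are handled explicitly:
bare dumps follow the strict-less-than routing convention of the external
tools, and their thresholds are single-precision values printed as shortest
decimals — so the importer snaps thresholds back to float32 and compares
features in float32, reproducing the original routing bit-for-bit (the test
suite verifies margin and attribution parity against the originating
booster). In-package exports wrap the same dialect with metadata
(`base_score`, feature names, routing rule) and stay in double precision.

## Baselines

* `gini_importance()`: per-feature sum of weighted impurity decreases,
  normalized to sum to one. For boosted ensembles, where nodes carry no
  class impurity, the summed quantity is each split's regularized loss
  reduction (its gain) — the standard ensemble analogue.
* `permutation_importance()`: drop in held-out accuracy (or log-loss, via
  `metric`) over `n_repeats = 10` seeded shuffles of one column at a time.
  A feature used by no split yields exactly zero drop.
* `partial_dependence()`: average predicted probability over a grid for one
  or two features; the grid is the observed unique values up to
  `grid_resolution = 50`, then equispaced quantiles — sweeping "every
  possible value" is impractical for continuous features.

## The synthetic generator

`make_synthetic()` emulates the structure the pipeline is meant to recover:
a binary outcome with a configurable class balance and Gaussian features,
where each informative feature's class-1 mean is shifted by a stated number
of noise standard deviations, with a known direction. It reproduces exactly
under a fixed seed. It does *not* emulate feature correlation, non-linear
or interaction effects, heavy tails, or the spatial structure of real
connectome matrices — so passing recovery tests demonstrates that the
pipeline identifies separated class means with the right rank, sign and
fold consistency, not that it untangles correlated predictors. The sign
rule itself assumes a monotone (linearizable) feature–outcome relationship;
features whose two classes differ in shape but not mean will be signed
unreliably, a known limitation inherited from the method.

The bundled `iris_binary()` table is the canonical 100-sample two-species
subset (versicolor = 0, virginica = 1) used as a small real-data check: the
petal dimensions dominate both classes' importances and all four features
appear in all five folds under the default seed.

## Numerical choices and degenerate inputs

* Filtering keeps confidence exactly at the threshold (strictly-below is
  dropped).
* An empty class partition yields all-zero weights with a warning rather
  than an error, so sparse folds degrade gracefully.
* Missing values are rejected everywhere: a decision path is undefined for
  a missing feature.
* Single-class labels, undersized folds (fewer than $k$ per class), and
  dimension mismatches are errors with explicit messages.
* Split-gain comparisons use a $10^{-12}$ slack so floating noise cannot
  reorder ties; zero-gain splits are not made.
* Probability-space trees refuse log-odds orientation; class prediction is
  1 exactly when the probability reaches 0.5.

## Problem sizes in the test suite

The suite's end-to-end checks run at sizes chosen to exercise the claims
while keeping a full run around a minute: conservation over 100 fits with
50 probes each; path-oracle equality on every leaf of 50 random trees;
planted-feature recovery over 20 seeded runs at $n = 500$ with a
3-standard-deviation shift and 50-tree, depth-3 ensembles (the recovery
target is rank, sign and 5/5 fold presence in at least 19 of 20 runs); and
one reduced-scale wide run at 60 samples by 379 features — the width of a
parcellation-level connectome table — to demonstrate that the pipeline
scales to that regime.

## Known limitations

Binary classification only (no multiclass softmax or regression
objectives); no missing-value routing; sign inference assumes monotone
effects; exact greedy split finding (no histogram approximation), which is
the right trade-off at the package's target scale but not for millions of
rows; and the per-class weights quantify association within the fitted
model, not causal effect.
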