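# hollowtree

Signed, magnitude-comparable, per-class feature importance for gradient
boosted binary classifiers — plus the per-prediction path decomposition it
is built on and the three baseline importance methods it is compared
against.

## The problem

Boosted tree models predict well but the standard importance summaries
each lose something essential. Gini (impurity-reduction) importance and
permutation importance rank features without saying whether a feature
pushes toward the positive or negative class; partial dependence plots are
directional but limited to one or two features at a time, which does not
scale to wide tables such as parcellation-level brain connectivity
matrices (hundreds of regions, tens of thousands of pairwise features).
This package implements a pipeline that keeps direction, magnitude and
scalability at once.

## The method

The building block is the exact additive decomposition of a single
prediction. Every tree node stores the expected model output of the
training samples routed through it; walking a sample's root-to-leaf path
and crediting each (child − parent) increment to the feature tested there
gives

    f(x) = bias + Σ_k contribution(x, k)

with the bias equal to the root expectation. For a single probability-space
tree the pieces sum to the predicted probability; for a boosted ensemble
the walk is summed across trees in log-odds space, where tree outputs are
additive, and internal-node expectations are reconstructed as
cover-weighted means of descendant leaves.

Per-prediction contributions become a global per-class importance by, per
stratified cross-validation fold: orienting each decomposition to its
predicted class, discarding incorrect and low-confidence predictions
(confidence max(p, 1−p) < 0.7), averaging contributions per feature within
each class over the retained predictions, and attaching a direction from
the sign of each feature's class-mean difference on the held-out split.
Fold results are averaged and each feature's fold-appearance count is
reported, so sporadically used but heavily weighted features stand out.

Everything is deterministic given a seed: the CART and Newton-boosting
trainers use exact greedy split search with fixed tie-breaks, and
externally trained boosters can be imported from the common JSON model-dump
dialect with bit-faithful routing.

## Worked example

The reference single-tree decomposition, built from its published node
values, for the probe flower (sepal length 6.9, sepal width 3.1, petal
length 4.9):

```r
library(hollowtree)
wx <- worked_example_tree()
decompose(wx$tree, wx$probe)
#> Decomposition of 1 prediction(s) in probability space (bias 0.493)
#>   probability predicted_class sepal_length sepal_width petal_length
#> 1           1               1        0.857      -0.107       -0.243
```

Read: starting from the root expectation 0.493, the sepal length raises
the virginica probability by 0.857, the sepal width lowers it by 0.107 and
the petal length by 0.243; the pieces sum to the predicted probability of
exactly 1. The identity `bias + Σ contributions = prediction` holds to
1e-9 for every model this package builds.

The full pipeline on the bundled two-class iris table:

```r
ib <- iris_binary()
fit <- hots(ib$X, ib$y, k = 5, seed = 1)
fit
#> HOTS feature importance: 4 features, 5-fold CV, confidence threshold 0.70
#> mean held-out accuracy: 0.950
#>        feature mean_positive mean_negative fold_count
#> 1 petal_length        4.0603       -4.2823          5
#> 2  petal_width        2.3865       -2.1369          5
#> 3 sepal_length       -0.0877        0.0206          5
#> 4  sepal_width        0.0520       -0.0215          5
```

The petal dimensions dominate both classes (in log odds, signed by the
class-mean rule: larger petals indicate the positive class, virginica),
the sepal dimensions carry little weight, and all four features are used
in all five folds. `summary(fit)` adds the per-fold columns,
`coef(fit)`/`plot(fit)` extract and draw the mean weights, and
`write_hots_report(fit, dir)` writes `importance.tsv` plus
`metrics.json`.

Baselines for comparison: `gini_importance(model)`,
`permutation_importance(model, X, y)` and
`partial_dependence(model, X, features)`.

A thin command-line wrapper lives at `inst/cli/hots_cli.R` with
subcommands `hots`, `explain`, `baselines` and `fixtures`; see the header
of that file for flags.

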