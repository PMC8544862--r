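# Baseline importance methods: Gini importance, permutation importance, and
# one-/two-dimensional partial dependence.

#' Impurity-reduction (Gini) feature importance
#'
#' For a probability-space tree, each split is credited with its weighted
#' impurity decrease `n * gini - n_left * gini_left - n_right * gini_right`;
#' credits are summed per feature and normalized to sum to one. For a boosted
#' ensemble, where nodes carry no class impurity, the analogous quantity is
#' the regularized loss reduction of each split (its gain), summed across all
#' trees and normalized the same way.
#'
#' @param model a `tree_model` or `boosted_trees` fit that recorded split
#'   statistics.
#' @return named numeric vector, non-negative, summing to 1 (all zero for a
#'   single-leaf model).
#' @export
gini_importance <- function(model) {
  trees <- if (inherits(model, "boosted_trees")) model$trees else list(model)
  feats <- if (inherits(model, "boosted_trees")) model$feature_names else model$feature_names
  imp <- structure(numeric(length(feats)), names = feats)
  for (tr in trees) {
    stopifnot(inherits(tr, "tree_model"))
    nd <- tr$nodes
    splits <- !is.na(nd$feature)
    if (!any(splits)) next
    if (anyNA(nd$gain[splits]) || anyNA(nd$n[splits])) {
      stop("split statistics missing: retrain with statistics (or re-export the dump with them)")
    }
    g <- tapply(nd$gain[splits], nd$feature[splits], sum)
    imp[as.integer(names(g))] <- imp[as.integer(names(g))] + g
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

#' Permutation feature importance
#'
#' Measures, for each feature, the drop in held-out performance when that
#' feature's column is shuffled while every other column keeps its order. A
#' feature the model never uses produces exactly zero drop, since predictions
#' are unchanged.
#'
#' @param model a `tree_model` (probability space) or `boosted_trees` fit.
#' @param X,y evaluation samples and their 0/1 labels.
#' @param n_repeats number of independent shuffles per feature.
#' @param seed integer seed for the shuffles.
#' @param metric `"accuracy"` (drop in accuracy) or `"logloss"` (increase in
#'   log-loss, reported as a positive drop).
#' @return data.frame with columns `feature`, `mean_drop`, `sd_drop`.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 10L, seed = 1L,
                                   metric = c("accuracy", "logloss")) {
  metric <- match.arg(metric)
  X <- as_feature_matrix(X)
  y <- check_labels(y, nrow(X), require_both_classes = FALSE)
  stopifnot(n_repeats >= 1)
  score <- function(M) {
    p <- model_probability(model, M)
    if (metric == "accuracy") {
      mean(as.integer(p >= 0.5) == y)
    } else {
      eps <- 1e-15
      mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
    }
  }
  base <- score(X)
  if (!is.null(seed)) set.seed(seed)
  drops <- matrix(NA_real_, n_repeats, ncol(X))
  for (j in seq_len(ncol(X))) {
    for (r in seq_len(n_repeats)) {
      Xp <- X
      Xp[, j] <- Xp[sample.int(nrow(X)), j]
      drops[r, j] <- base - score(Xp)
    }
  }
  data.frame(feature = colnames(X),
             mean_drop = colMeans(drops),
             sd_drop = apply(drops, 2, stats::sd),
             row.names = NULL)
}

model_probability <- function(model, X) {
  if (inherits(model, "boosted_trees")) {
    predict(model, X, type = "prob")
  } else if (inherits(model, "tree_model")) {
    if (model$value_space != "probability") {
      stop("probability predictions require a probability-space tree or an ensemble")
    }
    predict(model, X, type = "value")
  } else {
    stop("unsupported model type")
  }
}

#' Partial dependence of the model on one or two features
#'
#' Sweeps the chosen feature(s) over a grid while every other feature keeps
#' its observed values, and averages the model's predicted class-1
#' probability at each grid point. The grid is the sorted unique observed
#' values when there are at most `grid_resolution` of them, otherwise
#' `grid_resolution` equispaced quantiles. Limited to two features — the
#' dimensionality ceiling inherent to this visualization.
#'
#' @param model a `tree_model` (probability space) or `boosted_trees` fit.
#' @param X background feature matrix supplying the other columns.
#' @param features one or two feature indices or names.
#' @param grid_resolution maximum grid points per feature (>= 2).
#' @return object of class `partial_dependence`: `grid_1`, optional `grid_2`,
#'   `values` (vector, or matrix of `length(grid_1)` rows when two features),
#'   and `features` (the names). Has a `plot` method.
#' @export
partial_dependence <- function(model, X, features, grid_resolution = 50L) {
  X <- as_feature_matrix(X)
  if (is.character(features)) features <- match(features, colnames(X))
  features <- as.integer(features)
  if (anyNA(features) || any(features < 1 | features > ncol(X))) {
    stop("unknown feature(s)")
  }
  if (!length(features) %in% 1:2) {
    stop("partial dependence is limited to one or two features")
  }
  stopifnot(grid_resolution >= 2)
  grid_of <- function(x) {
    u <- sort(unique(x))
    if (length(u) <= grid_resolution) u else
      unique(stats::quantile(x, probs = seq(0, 1, length.out = grid_resolution),
                             names = FALSE, type = 7))
  }
  g1 <- grid_of(X[, features[1]])
  avg_at <- function(vals) {
    Xg <- X
    for (i in seq_along(features)) Xg[, features[i]] <- vals[i]
    mean(model_probability(model, Xg))
  }
  if (length(features) == 1L) {
    values <- vapply(g1, function(v) avg_at(v), numeric(1))
    g2 <- NULL
  } else {
    g2 <- grid_of(X[, features[2]])
    values <- outer(seq_along(g1), seq_along(g2),
                    Vectorize(function(i, j) avg_at(c(g1[i], g2[j]))))
    dimnames(values) <- list(signif(g1, 6), signif(g2, 6))
  }
  structure(list(grid_1 = g1, grid_2 = g2, values = values,
                 features = colnames(X)[features]),
            class = "partial_dependence")
}

#' @export
print.partial_dependence <- function(x, ...) {
  cat("Partial dependence of predicted probability on",
      paste(x$features, collapse = " x "), "\n")
  if (is.null(x$grid_2)) {
    print(data.frame(value = signif(x$grid_1, 6),
                     partial_dependence = signif(x$values, 6)))
  } else {
    print(signif(x$values, 4))
  }
  invisible(x)
}

#' @export
plot.partial_dependence <- function(x, ...) {
  if (is.null(x$grid_2)) {
    graphics::plot(x$grid_1, x$values, type = "s", xlab = x$features[1],
                   ylab = "partial dependence", ...)
  } else {
    graphics::filled.contour(x$grid_1, x$grid_2, x$values,
                             xlab = x$features[1], ylab = x$features[2], ...)
  }
  invisible(x)
}
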