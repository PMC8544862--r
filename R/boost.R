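# Gradient boosting for binary classification with logistic loss.
#
# Trees are fit to first/second order statistics (Newton boosting) with an L2
# leaf regularizer, the standard formulation of modern boosted-tree libraries:
# at a node with gradient sum G and hessian sum H, the optimal leaf weight is
# -G/(H + lambda) and a split's quality is
#   1/2 [ GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda) ].
# Leaf weights are scaled by the learning rate. After each tree is grown, the
# value of every internal node is set to the cover-weighted mean of its
# descendant leaves, which is the quantity the path decomposition differences.

best_newton_split <- function(X, g, h, rows, lambda, min_samples_split) {
  n <- length(rows)
  if (n < min_samples_split) return(NULL)
  G <- sum(g[rows]); H <- sum(h[rows])
  parent_score <- G^2 / (H + lambda)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xj <- X[rows, j]
    ord <- order(xj)
    xs <- xj[ord]
    cut_at <- which(xs[-n] < xs[-1])
    if (!length(cut_at)) next
    cg <- cumsum(g[rows][ord])
    ch <- cumsum(h[rows][ord])
    GL <- cg[cut_at]; HL <- ch[cut_at]
    GR <- G - GL;     HR <- H - HL
    gain <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - parent_score)
    k <- which.max(gain)
    if (gain[k] > 1e-12 && (is.null(best) || gain[k] > best$gain + 1e-12)) {
      thr <- (xs[cut_at[k]] + xs[cut_at[k] + 1]) / 2
      best <- list(feature = j, threshold = thr, gain = gain[k],
                   left_rows = rows[xj <= thr], right_rows = rows[xj > thr])
    }
  }
  best
}

grow_newton_tree <- function(X, g, h, lambda, learning_rate, max_depth,
                             min_samples_split) {
  nodes <- list()
  next_id <- 0L
  grow <- function(rows, depth) {
    next_id <<- next_id + 1L
    id <- next_id
    node <- data.frame(id = id, feature = NA_integer_, threshold = NA_real_,
                       left = NA_integer_, right = NA_integer_,
                       value = NA_real_, n = length(rows),
                       impurity = NA_real_, gain = NA_real_)
    sp <- if (depth < max_depth) {
      best_newton_split(X, g, h, rows, lambda, min_samples_split)
    }
    if (is.null(sp)) {
      node$value <- -sum(g[rows]) / (sum(h[rows]) + lambda) * learning_rate
      nodes[[id]] <<- node
      return(id)
    }
    node$feature <- sp$feature
    node$threshold <- sp$threshold
    node$gain <- sp$gain
    nodes[[id]] <<- node
    left_id <- grow(sp$left_rows, depth + 1L)
    right_id <- grow(sp$right_rows, depth + 1L)
    nodes[[id]]$left <<- left_id
    nodes[[id]]$right <<- right_id
    id
  }
  grow(seq_len(nrow(X)), 0L)
  fill_internal_values(do.call(rbind, nodes))
}

# Internal node value = cover-weighted mean of descendant leaf values.
fill_internal_values <- function(nodes) {
  idx <- match(seq_len(max(nodes$id)), nodes$id)
  fill <- function(id) {
    r <- idx[id]
    if (is.na(nodes$feature[r])) return(nodes$value[r])
    vl <- fill(nodes$left[r]); vr <- fill(nodes$right[r])
    nl <- nodes$n[idx[nodes$left[r]]]; nr <- nodes$n[idx[nodes$right[r]]]
    v <- (nl * vl + nr * vr) / (nl + nr)
    nodes$value[r] <<- v
    v
  }
  fill(nodes$id[1])
  nodes
}

new_boosted_ensemble <- function(trees, base_score, feature_names) {
  structure(
    list(trees = trees, base_score = base_score,
         n_features = length(feature_names),
         feature_names = as.character(feature_names)),
    class = "boosted_trees")
}

#' Fit a gradient boosted tree ensemble (binary logistic)
#'
#' Newton boosting with logistic loss: each round fits a regression tree to
#' the current gradient/hessian statistics, with L2-regularized leaf weights
#' scaled by the learning rate. All trees live in log-odds (margin) space; the
#' predicted probability is `plogis(base_score + sum of tree outputs)`. Split
#' search is exact and greedy over midpoint thresholds, so training is
#' deterministic.
#'
#' @param X numeric feature matrix or data frame.
#' @param y 0/1 labels, both classes present.
#' @param n_trees number of boosting rounds (>= 1).
#' @param learning_rate shrinkage applied to each leaf weight, in (0, 1].
#' @param max_depth maximum split levels per tree.
#' @param min_samples_split smallest node size eligible for splitting.
#' @param lambda L2 regularization on leaf weights.
#' @param base_score global log-odds offset (0 = prior probability 0.5).
#' @return object of class `boosted_trees`: a list of margin-space
#'   `tree_model`s plus `base_score`, with a `train_logloss` attribute giving
#'   the training log-loss after each round.
#' @examples
#' d <- make_synthetic(n_samples = 80, n_features = 3, informative = 1,
#'                     mean_shift = 2, seed = 1)
#' fit <- boosted_trees(d$X, d$y, n_trees = 10, max_depth = 2)
#' head(predict(fit, d$X, type = "prob"))
#' @export
boosted_trees <- function(X, y, n_trees = 100L, learning_rate = 0.3,
                          max_depth = 6L, min_samples_split = 2L,
                          lambda = 1, base_score = 0) {
  X <- as_feature_matrix(X)
  y <- check_labels(y, nrow(X))
  stopifnot(n_trees >= 1, learning_rate > 0, learning_rate <= 1,
            max_depth >= 1, min_samples_split >= 2, lambda >= 0)

  margin <- rep(base_score, nrow(X))
  trees <- vector("list", n_trees)
  logloss <- numeric(n_trees)
  for (m in seq_len(n_trees)) {
    p <- stats::plogis(margin)
    g <- p - y
    h <- p * (1 - p)
    nodes <- grow_newton_tree(X, g, h, lambda, learning_rate,
                              max_depth, min_samples_split)
    tr <- tree_model(nodes, colnames(X), value_space = "margin")
    trees[[m]] <- tr
    margin <- margin + predict(tr, X, type = "value")
    p_new <- stats::plogis(margin)
    eps <- 1e-15
    logloss[m] <- -mean(y * log(pmax(p_new, eps)) +
                          (1 - y) * log(pmax(1 - p_new, eps)))
  }
  ens <- new_boosted_ensemble(trees, base_score, colnames(X))
  attr(ens, "train_logloss") <- logloss
  ens
}

#' Predict from a boosted ensemble
#'
#' @param object a `boosted_trees` model.
#' @param newdata feature matrix/data frame, or a single feature vector.
#' @param type `"prob"` for the class-1 probability, `"margin"` for the raw
#'   log-odds (base score plus summed tree outputs), `"class"` for the 0/1
#'   label at probability 0.5 (class 1 when probability >= 0.5).
#' @param ... unused.
#' @return numeric (or integer) vector, one element per row.
#' @export
predict.boosted_trees <- function(object, newdata,
                                  type = c("prob", "margin", "class"), ...) {
  type <- match.arg(type)
  newdata <- as_newdata_matrix(newdata, object$n_features)
  margin <- rep(object$base_score, nrow(newdata))
  for (tr in object$trees) margin <- margin + predict(tr, newdata, type = "value")
  switch(type,
         margin = margin,
         prob = stats::plogis(margin),
         class = as.integer(stats::plogis(margin) >= 0.5))
}

#' @export
print.boosted_trees <- function(x, ...) {
  cat(sprintf("Boosted tree ensemble: %d trees, %d features, base score %.4g (log odds)\n",
              length(x$trees), x$n_features, x$base_score))
  invisible(x)
}
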