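test_that("a perfectly separable stump is recovered exactly", {
  fit <- cart_tree(cbind(x = c(0, 0, 1, 1)), c(0, 0, 1, 1), max_depth = 1)
  nd <- fit$nodes
  root <- nd[nd$id == fit$root_id, ]
  expect_equal(root$feature, 1L)
  expect_equal(root$value, 0.5)
  leaves <- sort(nd$value[is.na(nd$feature)])
  expect_equal(leaves, c(0, 1))
  expect_equal(predict(fit, cbind(x = c(0, 1))), c(0, 1))
})

test_that("degenerate or malformed training inputs are rejected", {
  X <- cbind(a = 1:4)
  expect_error(cart_tree(X, c(1, 1, 1, 1)), "degenerate labels")
  expect_error(boosted_trees(X, c(0, 0, 0, 0)), "degenerate labels")
  expect_error(cart_tree(data.frame(a = c("u", "v")), c(0, 1)), "non-numeric")
  expect_error(cart_tree(cbind(a = c(1, NA, 3, 4)), c(0, 1, 0, 1)), "missing values")
})

test_that("CART split choice matches exhaustive enumeration of all candidates", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(round(rnorm(40), 2), 20, 2, dimnames = list(NULL, c("a", "b")))
    y <- as.integer(X[, 1] - 0.5 * X[, 2] + rnorm(20, sd = 0.6) > 0)
    if (length(unique(y)) < 2) next
    fit <- cart_tree(X, y, max_depth = 1)
    root <- fit$nodes[fit$nodes$id == fit$root_id, ]
    oracle <- oracle_best_split(X, y)
    expect_equal(root$feature, oracle$feature)
    expect_equal(root$threshold, oracle$threshold)
    expect_equal(root$gain, oracle$gain, tolerance = 1e-12)
  }
})

test_that("trained node values equal the class-1 fraction of routed rows", {
  pr <- random_problem(n = 80, p = 3, seed = 4)
  fit <- cart_tree(pr$X, pr$y, max_depth = 4)
  nd <- fit$nodes
  # route rows to every node, not just leaves, by walking constraints per row
  reach <- matrix(FALSE, nrow(pr$X), nrow(nd))
  reach[, match(fit$root_id, nd$id)] <- TRUE
  for (r in order(nd$id)) {
    if (is.na(nd$feature[r])) next
    rows <- which(reach[, r])
    go_left <- pr$X[rows, nd$feature[r]] <= nd$threshold[r]
    reach[rows[go_left], match(nd$left[r], nd$id)] <- TRUE
    reach[rows[!go_left], match(nd$right[r], nd$id)] <- TRUE
  }
  for (r in seq_len(nrow(nd))) {
    rows <- which(reach[, r])
    expect_equal(nd$n[r], length(rows))
    expect_equal(nd$value[r], mean(pr$y[rows]))
  }
})

test_that("trees satisfy structural validity: single root, one parent each, leaves = internals + 1", {
  for (seed in 1:5) {
    pr <- random_problem(n = 50, p = 3, seed = seed)
    fit <- cart_tree(pr$X, pr$y, max_depth = 3)
    expect_silent(validate_tree_model(fit))
    nd <- fit$nodes
    expect_equal(sum(is.na(nd$feature)), sum(!is.na(nd$feature)) + 1L)
    kids <- c(nd$left, nd$right)
    kids <- kids[!is.na(kids)]
    expect_false(any(duplicated(kids)))
    expect_false(fit$root_id %in% kids)
  }
  bad <- worked_example_tree()$tree
  bad$nodes$left[1] <- 99L
  expect_error(validate_tree_model(bad), "malformed tree")
})

test_that("boosted training log-loss is non-increasing per added tree", {
  d <- make_synthetic(n_samples = 150, n_features = 4, informative = 1,
                      mean_shift = 2, seed = 3)
  fit <- boosted_trees(d$X, d$y, n_trees = 15, max_depth = 3)
  ll <- attr(fit, "train_logloss")
  expect_length(ll, 15)
  expect_true(all(diff(ll) <= 1e-9))
  # and the recorded log-loss matches recomputation from partial ensembles
  partial <- new_boosted_ensemble(fit$trees[1:7], fit$base_score, fit$feature_names)
  p <- predict(partial, d$X, type = "prob")
  expect_equal(ll[7], -mean(d$y * log(p) + (1 - d$y) * log(1 - p)), tolerance = 1e-9)
})

test_that("ensemble probability is the logistic of base score plus summed tree margins", {
  d <- make_synthetic(n_samples = 80, n_features = 3, informative = 1,
                      mean_shift = 1.5, seed = 9)
  fit <- boosted_trees(d$X, d$y, n_trees = 8, max_depth = 3, base_score = 0.25)
  margin <- rep(fit$base_score, nrow(d$X))
  for (tr in fit$trees) margin <- margin + predict(tr, d$X, type = "value")
  expect_equal(predict(fit, d$X, type = "prob"), plogis(margin), tolerance = 1e-12)
  expect_equal(predict(fit, d$X, type = "margin"), margin, tolerance = 1e-12)
})

test_that("one-round boosting at learning rate 1 separates separable data; margins scale with the rate", {
  X <- cbind(x = c(-2, -1.5, -1, 1, 1.5, 2))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- boosted_trees(X, y, n_trees = 1, learning_rate = 1, max_depth = 2)
  expect_equal(as.integer(predict(fit, X, type = "margin") > 0), y)
  f1 <- boosted_trees(X, y, n_trees = 1, learning_rate = 1, max_depth = 2)
  f3 <- boosted_trees(X, y, n_trees = 1, learning_rate = 0.3, max_depth = 2)
  expect_equal(predict(f3, X, type = "margin"),
               0.3 * predict(f1, X, type = "margin"), tolerance = 1e-12)
})

test_that("internal margin-tree values are cover-weighted means of descendant leaves", {
  d <- make_synthetic(n_samples = 100, n_features = 3, informative = 1,
                      mean_shift = 2, seed = 6)
  fit <- boosted_trees(d$X, d$y, n_trees = 3, max_depth = 3)
  for (tr in fit$trees) {
    nd <- tr$nodes
    for (r in which(!is.na(nd$feature))) {
      l <- match(nd$left[r], nd$id); rr <- match(nd$right[r], nd$id)
      expect_equal(nd$value[r],
                   (nd$n[l] * nd$value[l] + nd$n[rr] * nd$value[rr]) / (nd$n[l] + nd$n[rr]),
                   tolerance = 1e-12)
      expect_equal(nd$n[r], nd$n[l] + nd$n[rr])
    }
  }
})

test_that("prediction rejects inputs of the wrong width", {
  pr <- random_problem(seed = 2)
  fit <- cart_tree(pr$X, pr$y, max_depth = 2)
  expect_error(predict(fit, c(1, 2)), "dimension error")
  expect_error(predict(fit, matrix(0, 2, 5)), "dimension error")
})
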