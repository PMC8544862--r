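test_that("filtering keeps exactly the correct, confident predictions", {
  # 10 predictions: 6 correct with confidence >= 0.7, 2 correct below, 2 wrong
  prob <- c(0.95, 0.9, 0.8, 0.75, 0.12, 0.3, 0.69, 0.42, 0.97, 0.05)
  true <- c(1,    1,   1,   1,    0,    0,   1,    0,    0,    1)
  d <- fake_decomposition(matrix(seq_len(20), 10, 2), prob, true)
  kept <- filter_predictions(d, 0.7)
  expect_equal(kept$sample_id, as.character(c(1, 2, 3, 4, 5, 6)))
  # boundary: confidence exactly at the threshold is retained, strictly below is not
  d2 <- fake_decomposition(matrix(0, 2, 1), c(0.70, 0.69), c(1, 1))
  expect_equal(filter_predictions(d2, 0.7)$sample_id, "1")
  # empty input stays empty; missing labels are an error
  empty <- fake_decomposition(matrix(0, 0, 2), numeric(), integer())
  expect_equal(n_samples(filter_predictions(empty, 0.7)), 0L)
  expect_error(filter_predictions(fake_decomposition(matrix(0, 1, 1), 0.9), 0.7),
               "true_class")
})

test_that("raising the confidence threshold never adds retained predictions", {
  set.seed(42)
  prob <- runif(50)
  true <- rbinom(50, 1, 0.5)
  d <- fake_decomposition(matrix(rnorm(100), 50, 2), prob, true)
  sizes <- vapply(seq(0, 1, by = 0.05),
                  function(t) n_samples(filter_predictions(d, t)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("class partition matches a hand enumeration and orients contributions", {
  prob <- c(0.9, 0.8, 0.2, 0.1, 0.95, 0.25)
  d <- fake_decomposition(matrix(1, 6, 2), prob, true_class = c(1, 1, 0, 0, 1, 0))
  parts <- split_by_class(d)
  expect_equal(parts$positive$sample_id, c("1", "2", "5"))
  expect_equal(parts$negative$sample_id, c("3", "4", "6"))
  expect_equal(n_samples(parts$positive) + n_samples(parts$negative), 6L)
  # negative-class rows carry log odds of class 0: the raw values negated
  expect_true(all(parts$negative$contributions == -1))
  expect_true(all(parts$positive$contributions == 1))
})

test_that("aggregation averages contributions per retained prediction", {
  d <- fake_decomposition(rbind(c(1, 0), c(0.5, 0.5), c(1.5, -0.5)),
                          c(0.9, 0.9, 0.9), c(1, 1, 1))
  expect_equal(unname(aggregate_weights(d)), c(1, 0))
  one <- fake_decomposition(rbind(c(0.3, -0.2)), 0.8, 1)
  expect_equal(unname(aggregate_weights(one)), c(0.3, -0.2))
  empty <- fake_decomposition(matrix(0, 0, 2), numeric(), integer())
  expect_warning(w <- aggregate_weights(empty), "no retained predictions")
  expect_equal(unname(w), c(0, 0))
})

test_that("sign inference applies the class-mean rule, zeroing ties and flipping with negated data", {
  X <- cbind(a = c(1, 2, 5, 6), b = c(3, 3, 3, 3))
  y <- c(0, 0, 1, 1)
  expect_warning(s <- infer_signs(c(a = 0.8, b = 0.5), c(a = 0.6, b = 0.4), X, y),
                 "equal class means")
  expect_equal(unname(s$positive_weights), c(0.8, 0))   # mean_pos > mean_neg: +s
  expect_equal(unname(s$negative_weights), c(-0.6, 0))  # inverse sign for the negative class
  Xn <- X; Xn[, "a"] <- -Xn[, "a"]
  expect_warning(sn <- infer_signs(c(a = 0.8, b = 0.5), c(a = 0.6, b = 0.4), Xn, y))
  expect_equal(sn$positive_weights[["a"]], -0.8)
  expect_equal(sn$negative_weights[["a"]], 0.6)
  expect_error(infer_signs(c(a = 1, b = 1), c(a = 1, b = 1), X, c(1, 1, 1, 1)),
               "cannot compute class means")
})

test_that("HOTS recovers a planted informative feature with the planted direction", {
  d <- make_synthetic(n_samples = 300, n_features = 5, informative = 2,
                      mean_shift = 3, seed = 14)
  h <- hots(d$X, d$y, k = 5, n_trees = 30, max_depth = 3, seed = 14)
  expect_equal(which.max(abs(h$mean_positive)), c(f2 = 2L))
  expect_gt(h$mean_positive[["f2"]], 0)       # class-1 mean is higher: positive direction
  expect_lt(h$mean_negative[["f2"]], 0)
  expect_equal(fold_counts(h)[["f2"]], 5L)
  expect_equal(h$mean_accuracy, mean(h$per_fold_accuracy))
})

test_that("stratified folds are disjoint, cover all samples and balance classes", {
  d <- make_synthetic(n_samples = 103, n_features = 3, informative = 1,
                      mean_shift = 1, class_balance = 0.4, seed = 5)
  h <- hots(d$X, d$y, k = 5, n_trees = 5, max_depth = 2, seed = 5)
  expect_equal(length(h$folds), 103L)
  expect_equal(sum(table(h$folds)), 103L)
  for (i in 1:5) expect_true(all(table(d$y[h$folds == i]) >= 1))
  sizes <- table(h$folds)
  expect_lte(max(sizes) - min(sizes), 2)
})

test_that("relabeling y to 1 - y swaps the positive and negative signed weight vectors exactly", {
  d <- make_synthetic(n_samples = 200, n_features = 4, informative = 1,
                      mean_shift = 2, seed = 5)
  set.seed(11)
  folds <- make_folds(d$y, 4)
  h1 <- hots(d$X, d$y, k = 4, n_trees = 20, max_depth = 3, folds = folds)
  h2 <- hots(d$X, 1L - d$y, k = 4, n_trees = 20, max_depth = 3, folds = folds)
  expect_equal(h1$mean_positive, h2$mean_negative, tolerance = 1e-12)
  expect_equal(h1$mean_negative, h2$mean_positive, tolerance = 1e-12)
  expect_identical(fold_counts(h1), fold_counts(h2))
  expect_equal(h1$per_fold_accuracy, h2$per_fold_accuracy)
})

test_that("fold counts count folds with nonzero weight in either class, bounded by k", {
  h <- structure(list(fold_counts = c(a = 0L, b = 3L)), class = "hots")
  expect_equal(fold_counts(h), c(a = 0L, b = 3L))
  d <- make_synthetic(n_samples = 150, n_features = 6, informative = 1,
                      mean_shift = 3, seed = 20)
  fit <- hots(d$X, d$y, k = 5, n_trees = 10, max_depth = 2, seed = 20)
  expect_true(all(fold_counts(fit) >= 0 & fold_counts(fit) <= 5))
  # recompute counts from the stored per-fold weights
  pos <- do.call(rbind, lapply(fit$per_fold, `[[`, "positive_weights"))
  neg <- do.call(rbind, lapply(fit$per_fold, `[[`, "negative_weights"))
  expect_equal(unname(fold_counts(fit)),
               unname(colSums(pmax(abs(pos), abs(neg)) > fit$appearance_epsilon)))
})

test_that("HOTS run is reproducible for a fixed seed and errors on undersized input", {
  d <- make_synthetic(n_samples = 120, n_features = 3, informative = 1,
                      mean_shift = 2, seed = 2)
  h1 <- hots(d$X, d$y, k = 3, n_trees = 8, max_depth = 2, seed = 99)
  h2 <- hots(d$X, d$y, k = 3, n_trees = 8, max_depth = 2, seed = 99)
  expect_equal(h1$mean_positive, h2$mean_positive, tolerance = 0)
  expect_equal(h1$folds, h2$folds)
  expect_error(hots(d$X[1:6, ], d$y[1:6], k = 5), "too few samples")
})

test_that("summary/coef/report expose the per-fold table and mean weights", {
  d <- make_synthetic(n_samples = 120, n_features = 5, informative = 1,
                      mean_shift = 2.5, seed = 31)
  h <- hots(d$X, d$y, k = 3, n_trees = 10, max_depth = 2, seed = 31)
  s <- summary(h)
  expect_true(all(c("feature", "mean_positive", "mean_negative", "fold_count",
                    "pos_fold1", "neg_fold3") %in% names(s)))
  expect_equal(nrow(s), 5L)
  # per-fold columns carry the fold vectors feature-by-feature
  expect_equal(s$pos_fold2[s$feature == "f1"],
               h$per_fold[[2]]$positive_weights[["f1"]])
  expect_equal(unname(coef(h, "positive")), unname(h$mean_positive))
  expect_equal(dim(coef(h)), c(5L, 2L))
  out <- file.path(tempdir(), "hots-report")
  paths <- write_hots_report(h, out)
  expect_true(all(file.exists(paths)))
  tab <- read.delim(paths[["importance"]])
  expect_equal(nrow(tab), 5L)
  met <- jsonlite::fromJSON(paths[["metrics"]])
  expect_equal(met$mean$accuracy, h$mean_accuracy)
})
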