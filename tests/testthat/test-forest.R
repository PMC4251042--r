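test_that("entropy and information gain match hand-computed closed forms", {
  expect_equal(entropy_bits(c(2, 2)), 1)
  expect_equal(entropy_bits(c(4, 0)), 0)
  expect_equal(entropy_bits(c(1, 3)), 0.81128, tolerance = 1e-5)
  expect_equal(entropy_bits(c(1, 3)), -0.25 * log2(0.25) - 0.75 * log2(0.75))
  expect_error(entropy_bits(c(0, 0)), "all-zero")
  expect_error(entropy_bits(c(-1, 2)), "nonnegative")

  expect_equal(information_gain(c(2, 2), c(2, 0), c(0, 2)), 1)
  expect_equal(information_gain(c(4, 2), c(2, 1), c(2, 1)), 0)
  expect_equal(information_gain(c(3, 1), c(2, 0), c(1, 1)), 0.31128,
               tolerance = 1e-5)
  expect_error(information_gain(c(3, 1), c(1, 0), c(1, 1)), "sum to the parent")
})

test_that("a separable dataset is fit by a single split with zero error", {
  x <- matrix(c(1, 2, 3, 10, 11, 12, 5, 5, 5, 5, 5, 5), ncol = 2)
  colnames(x) <- c("x1", "x2")
  y <- c(0, 0, 0, 1, 1, 1)
  tree <- train_tree(x, y)
  expect_equal(predict(tree, x, type = "class"), y)
  expect_equal(length(tree$tree$feature), 3)  # root + two leaves
  expect_equal(tree$tree$feature[1], 1L)
})

test_that("degenerate nodes become leaves with observed class fractions", {
  # identical features, mixed labels: no valid split
  x <- matrix(1, nrow = 4, ncol = 2, dimnames = list(NULL, c("a", "b")))
  tree <- train_tree(x, c(0, 1, 1, 1))
  expect_equal(length(tree$tree$feature), 1)
  expect_equal(predict(tree, x)[1], 0.75)
  # XOR: no single-feature split has positive gain -> single leaf at 0.5
  xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  xor_tree <- train_tree(xor_x, c(0, 1, 1, 0))
  expect_equal(length(xor_tree$tree$feature), 1)
  expect_equal(predict(xor_tree, xor_x), rep(0.5, 4))
})

test_that("values on a threshold boundary are routed to the left branch", {
  x <- matrix(c(0, 0, 1, 1), ncol = 1, dimnames = list(NULL, "x1"))
  tree <- train_tree(x, c(0, 0, 1, 1))
  expect_equal(tree$tree$threshold[1], 0.5)
  expect_equal(predict(tree, matrix(0.5, dimnames = list(NULL, "x1"))), 0)
})

test_that("the chosen split maximises information gain (exhaustive re-scan)", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- 20
      x <- matrix(sample(1:8, n * 3, replace = TRUE) + 0, ncol = 3,
                  dimnames = list(NULL, paste0("f", 1:3)))
      y <- sample(0:1, n, replace = TRUE)
      if (length(unique(y)) < 2) next
      tree <- suppressWarnings(
        train_tree(x, y, params = forest_params(
          n_trees = 1, bootstrap = FALSE, n_features_sampled = "all",
          max_depth = 1, seed = rep))
      )
      # brute-force re-scan of every feature x midpoint threshold
      parent <- c(sum(y == 0), sum(y == 1))
      best_seen <- 0
      for (f in 1:3) {
        vals <- sort(unique(x[, f]))
        if (length(vals) < 2) next
        for (thr in (vals[-1] + vals[-length(vals)]) / 2) {
          l <- y[x[, f] <= thr]
          r <- y[x[, f] > thr]
          g <- information_gain(parent, c(sum(l == 0), sum(l == 1)),
                                c(sum(r == 0), sum(r == 1)))
          expect_gte(g, 0)
          best_seen <- max(best_seen, g)
        }
      }
      if (!is.na(tree$tree$feature[1])) {
        f <- tree$tree$feature[1]
        thr <- tree$tree$threshold[1]
        l <- y[x[, f] <= thr]
        r <- y[x[, f] > thr]
        g_chosen <- information_gain(parent, c(sum(l == 0), sum(l == 1)),
                                     c(sum(r == 0), sum(r == 1)))
        expect_equal(g_chosen, best_seen, tolerance = 1e-12)
      } else {
        expect_lte(best_seen, 1e-12)
      }
    }
  })
})

test_that("forest probability is the arithmetic mean of tree probabilities", {
  f <- leaf_forest(c(0.2, 0.4, 0.9))
  x <- matrix(0, dimnames = list(NULL, "x1"))
  expect_identical(predict(f, x), (0.2 + 0.4 + 0.9) / 3)
  unanimous <- leaf_forest(c(1, 1, 1))
  expect_identical(predict(unanimous, x), 1)
  expect_equal(predict(unanimous, x, type = "class"), 1L)
  # exact 0.5 ties go to class 0 (the majority class)
  tied <- leaf_forest(c(0.25, 0.75))
  expect_identical(predict(tied, x), 0.5)
  expect_equal(predict(tied, x, type = "class"), 0L)
})

test_that("a 1-tree unbagged full-feature forest equals a single tree", {
  withr::with_seed(33, {
    for (rep in 1:20) {
      n <- 30
      x <- matrix(rnorm(n * 4), ncol = 4, dimnames = list(NULL, paste0("f", 1:4)))
      y <- as.integer(x[, 1] + rnorm(n, sd = 0.5) > 0)
      if (length(unique(y)) < 2) next
      params <- forest_params(n_trees = 1, bootstrap = FALSE,
                              n_features_sampled = "all", seed = rep)
      forest <- train_forest(x, y, params = params)
      tree <- train_tree(x, y, params = params)
      expect_identical(predict(forest, x), predict(tree, x))
    }
  })
})

test_that("training is deterministic given the seed", {
  withr::with_seed(8, {
    x <- matrix(rnorm(200), ncol = 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- as.integer(x[, 2] > 0)
  })
  p <- forest_params(n_trees = 10, seed = 99)
  f1 <- train_forest(x, y, params = p)
  f2 <- train_forest(x, y, params = p)
  expect_identical(f1$trees, f2$trees)
  f3 <- train_forest(x, y, params = forest_params(n_trees = 10, seed = 100))
  expect_false(identical(f1$trees, f3$trees))
})

test_that("forests warn on single-class training labels", {
  x <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(train_forest(x, rep(1L, 10),
                              params = forest_params(n_trees = 2, seed = 1)),
                 "single class")
})

test_that("prediction validates the feature dimension and names", {
  x <- matrix(rnorm(40), ncol = 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(x[, 1] > 0)
  forest <- train_forest(x, y, params = forest_params(n_trees = 3, seed = 2))
  expect_error(predict(forest, matrix(0, ncol = 3)), "dimension mismatch")
  bad <- as.data.frame(x)
  names(bad)[2] <- "oops"
  expect_error(predict(forest, bad), "oops|lacks feature")
})

test_that("serialization round-trips bit for bit", {
  feats <- tiny_features()
  forest <- train_forest(feats, params = forest_params(n_trees = 5, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  rf_save(forest, path)
  restored <- rf_load(path)
  expect_identical(restored$trees, forest$trees)
  expect_identical(restored$feature_names, forest$feature_names)
  Xnew <- as.matrix(feats[1:50, foldrec:::feature_cols(feats)])
  expect_identical(predict(restored, Xnew), predict(forest, Xnew))
  # a second save of the restored model produces identical bytes
  path2 <- withr::local_tempfile(fileext = ".json")
  rf_save(restored, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("per-tree and per-split sampling both train working forests", {
  feats <- tiny_features()
  for (mode in c("per_split", "per_tree")) {
    f <- train_forest(feats, params = forest_params(
      n_trees = 10, feature_sampling = mode, seed = 4))
    expect_length(f$trees, 10)
    prob <- predict(f, feats)
    expect_true(all(prob >= 0 & prob <= 1))
  }
})

test_that("tidy and glance summarise forests", {
  feats <- tiny_features()
  f <- train_forest(feats, params = forest_params(n_trees = 4, seed = 5))
  td <- tidy(f)
  expect_equal(nrow(td), 4)
  expect_true(all(td$n_leaves >= 1))
  g <- glance(f)
  expect_equal(g$n_trees, 4)
  expect_equal(g$n_features, length(foldrec:::feature_cols(feats)))
})

test_that("accuracy is comparable to an established forest implementation", {
  skip_if_not_installed("randomForest")
  withr::with_seed(19, {
    n <- 300
    x <- matrix(rnorm(n * 4), ncol = 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- as.integer(x[, 1] + 0.8 * x[, 2] + rnorm(n, sd = 0.6) > 0)
    train <- 1:200
    test <- 201:n
    ours <- train_forest(x[train, ], y[train],
                         params = forest_params(n_trees = 100, seed = 7))
    acc_ours <- mean(predict(ours, x[test, ], type = "class") == y[test])
    ref <- randomForest::randomForest(x[train, ], factor(y[train]), ntree = 100)
    acc_ref <- mean(as.integer(as.character(predict(ref, x[test, ]))) == y[test])
    expect_gt(acc_ours, 0.8)
    expect_gt(acc_ours, acc_ref - 0.1)
  })
})
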