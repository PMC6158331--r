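# Random Forest: Gini arithmetic, split search, voting, bagging behavior.

test_that("Gini impurity decrease matches the formula", {
  expect_equal(gini_impurity_decrease(c(4, 0), c(2, 0), c(2, 0)), 0)
  expect_equal(gini_impurity_decrease(c(5, 5), c(5, 0), c(0, 5)), 0.5)
  expect_error(gini_impurity_decrease(c(0, 0), c(0, 0), c(0, 0)), "empty")
  expect_error(gini_impurity_decrease(c(2, 2), c(2, 0), c(1, 2)), "equal")

  set.seed(8)
  for (i in 1:50) {
    l <- rpois(2, 4)
    r <- rpois(2, 4)
    p <- l + r
    if (sum(p) == 0) next
    g <- function(cnt) if (sum(cnt) == 0) 0 else 1 - sum((cnt / sum(cnt))^2)
    direct <- g(p) - sum(l) / sum(p) * g(l) - sum(r) / sum(p) * g(r)
    expect_equal(gini_impurity_decrease(p, l, r), direct)
  }
})

test_that("default mtry is the square-root ceiling (4 of 10)", {
  expect_identical(rf_default_mtry(10), 4L)
  expect_identical(rf_default_mtry(16), 4L)
  expect_identical(rf_default_mtry(40), 7L)
})

test_that("a perfectly separable feature yields unanimous training votes", {
  set.seed(9)
  n <- 40
  x <- cbind(sep = c(rnorm(n, -5), rnorm(n, 5)),
             noise = rnorm(2 * n))
  y <- rep(c(0, 1), each = n)
  m <- rf_train(x, y, n_trees = 30, mtry = 2, seed = 1)
  v <- rf_score(m, x)
  expect_true(all(v[y == 0] == 0))
  expect_true(all(v[y == 1] == 1))
  expect_error(rf_train(x, rep(1, 2 * n), n_trees = 5), "both classes")
})

test_that("a depth-limited stump recovers the exhaustive Gini-optimal split", {
  # 4-point 1-D set; brute-force over midpoint thresholds
  x <- matrix(c(1, 2, 10, 11), ncol = 1)
  y <- c(0, 0, 1, 1)
  m <- rf_train(x, y, n_trees = 1, mtry = 1, min_node = 2, seed = 3)
  tree <- m$trees[[1]]
  # independent exhaustive search
  g <- function(cnt) if (sum(cnt) == 0) 0 else 1 - sum((cnt / sum(cnt))^2)
  best <- -Inf
  best_thr <- NA
  xs <- sort(unique(x))
  for (thr in (xs[-1] + xs[-length(xs)]) / 2) {
    left <- y[x <= thr]
    right <- y[x > thr]
    dec <- g(table(factor(y, 0:1))) -
      length(left) / 4 * g(table(factor(left, 0:1))) -
      length(right) / 4 * g(table(factor(right, 0:1)))
    if (dec > best + 1e-12) { best <- dec; best_thr <- thr }
  }
  # the bootstrap resamples the 4 points, but with this geometry every
  # bootstrap containing both classes splits in the wide gap
  expect_gt(tree$threshold[1], 2)
  expect_lt(tree$threshold[1], 10)
  expect_equal(best_thr, 6)
})

test_that("vote fraction equals the mean of per-tree predictions", {
  m <- tiny_forest()
  tr <- tiny_train()
  x <- tr$x[seq(1, nrow(tr$x), length.out = 25), , drop = FALSE]
  votes <- rf_score(m, x)
  per_tree <- sapply(m$trees, function(tree) {
    apply(x, 1, function(row) {
      node <- 1L
      while (tree$feature[node] >= 0) {
        node <- if (row[tree$feature[node] + 1] <= tree$threshold[node])
          node + 1L else tree$right[node] + 1L
      }
      tree$label[node]
    })
  })
  expect_equal(votes, rowMeans(per_tree))
  expect_true(all(votes >= 0 & votes <= 1))
})

test_that("training is deterministic under a fixed seed", {
  tr <- tiny_train()
  m1 <- rf_train(tr$x, tr$y, n_trees = 10, seed = 99)
  m2 <- rf_train(tr$x, tr$y, n_trees = 10, seed = 99)
  expect_identical(m1$trees, m2$trees)
  m3 <- rf_train(tr$x, tr$y, n_trees = 10, seed = 100)
  expect_false(identical(m1$trees, m3$trees))
})

test_that("bootstrap leaves about a third of rows out of bag", {
  # measured through the OOB machinery: with many trees, the fraction of
  # trees for which a given row is OOB approaches exp(-1)
  set.seed(10)
  n <- 200
  x <- matrix(rnorm(n * 2), n, 2)
  y <- rep(c(0, 1), n / 2)
  m <- rf_train(x, y, n_trees = 150, mtry = 1, seed = 5)
  # reconstruct OOB fractions by predicting: not directly exposed, so use
  # a direct simulation of the same sampler instead
  draws <- replicate(500, length(unique(sample.int(n, n, replace = TRUE))))
  expect_equal(mean(draws) / n, 1 - exp(-1), tolerance = 0.01)
  expect_true(is.finite(m$oob_error))
})

test_that("RF beats line length on amplitude-neutral spectral seizures", {
  # seizures that only redistribute power across bands: band-power features
  # give the forest an edge over the amplitude-driven line-length detector
  cfg <- synth_config(block_duration_s = 300, lvfa_amplitude_neutral = TRUE,
                      drift_amp = 0, seed = 77)
  recs <- synth_dataset(4, cfg, seed = 77)
  blocks <- prepare_blocks(recs)
  auc_ll <- run_detector(blocks, "ll", "single")$auc
  auc_rf <- run_detector(blocks, "rf", "single", seed = 77)$auc
  expect_gt(auc_rf, 0.5)
  expect_gte(auc_rf, auc_ll)
})
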