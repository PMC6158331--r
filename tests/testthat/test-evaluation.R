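# ROC/AUC, early relabeling, delay, sensitivity, FDR, LOSO-CV.

test_that("AUC handles separation, ties, and matches all-pairs counting", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "undefined")

  set.seed(14)
  for (i in 1:30) {
    s <- sample(1:6, 40, replace = TRUE)  # heavy ties
    l <- runif(40) < 0.4
    if (!any(l) || all(l)) next
    pairs <- expand.grid(p = s[l], n = s[!l])
    oracle <- mean((pairs$p > pairs$n) + 0.5 * (pairs$p == pairs$n))
    expect_equal(roc_auc(s, l)$auc, oracle)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(15)
  s <- rnorm(100)
  l <- runif(100) < 0.3
  a <- roc_auc(s, l)$auc
  expect_equal(roc_auc(exp(2 * s + 1), l)$auc, a)
  expect_equal(roc_auc(rank(s), l)$auc, a)
})

test_that("z-scored and raw line length give identical ROCs", {
  blocks <- tiny_blocks()$blocks
  ll <- blocks[[1]]$features[, 1, "line_length"]
  lab <- blocks[[1]]$labels
  m <- ll_model(ll)
  expect_equal(roc_auc(ll_score(m, ll), lab)$auc, roc_auc(ll, lab)$auc)
  z <- ll_score(m, ll)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_equal(ll_score(m, m$mu), 0)
  expect_error(ll_model(rep(2, 10)), "degenerate")
})

test_that("early relabeling keeps the first-window epochs and excludes the rest", {
  labels <- c(rep(FALSE, 20), rep(TRUE, 30), rep(FALSE, 10))
  starts <- 0:59
  out <- early_relabel(labels, starts, onset_s = 20, early_window_s = 10)
  expect_equal(sum(out, na.rm = TRUE), 10)
  expect_equal(sum(is.na(out)), 20)
  expect_equal(which(out), 21:30)

  short <- early_relabel(rep(c(FALSE, TRUE), c(5, 6)), 0:10, onset_s = 5,
                         early_window_s = 10)
  expect_equal(sum(short, na.rm = TRUE), 6)
  expect_equal(sum(is.na(short)), 0)
})

test_that("a late-firing detector loses more early AUC than whole AUC", {
  labels <- c(rep(FALSE, 50), rep(TRUE, 30), rep(FALSE, 20))
  starts <- 0:99
  set.seed(16)
  score <- rnorm(100, 0, 0.1)
  score[61:80] <- 5  # fires only from 10 s into the seizure
  whole <- roc_auc(score, labels)$auc
  el <- early_relabel(labels, starts, onset_s = 50, early_window_s = 10)
  early <- roc_auc(score[!is.na(el)], el[!is.na(el)])$auc
  expect_lt(early, whole)
})

test_that("detection delay follows the epoch-counting rules", {
  starts <- 0:99
  labels <- starts >= 30 & starts < 60
  det <- rep(FALSE, 100)

  det[31] <- TRUE  # first ictal epoch
  expect_equal(detection_delay(det, labels, starts, 30), 1)

  det <- rep(FALSE, 100)
  det[28] <- TRUE  # 2 s before onset, inside tolerance
  expect_equal(detection_delay(det, labels, starts, 30), 0)

  det <- rep(FALSE, 100)
  det[35] <- TRUE  # 5th ictal epoch
  expect_equal(detection_delay(det, labels, starts, 30), 5)

  det <- rep(FALSE, 100)
  det[90] <- TRUE  # after seizure end: miss
  expect_true(is.na(detection_delay(det, labels, starts, 30)))

  det[20] <- TRUE  # before tolerance window: still a miss
  expect_true(is.na(detection_delay(det, labels, starts, 30)))
})

test_that("sensitivity counts non-missed seizures", {
  expect_equal(sensitivity(c(1, 0, 3, NA, 2, 0, 1, NA, 4, 1)), 0.8)
  expect_equal(sensitivity(rep(NA_real_, 4)), 0)
  expect_error(sensitivity(numeric(0)), "at least one")
})

test_that("FDR counts events per analyzed hour, merging optional", {
  starts <- 0:3599
  labels <- rep(FALSE, 3600)
  det <- rep(FALSE, 3600)
  det[c(100, 500, 900)] <- TRUE
  f <- fdr_per_hour(det, labels, starts, onset_s = numeric(0))
  expect_equal(f$rate, 3)

  det <- rep(FALSE, 3600)
  det[100:104] <- TRUE
  expect_equal(fdr_per_hour(det, labels, starts, numeric(0))$rate, 1)
  f2 <- fdr_per_hour(det, labels, starts, numeric(0), event_merge = FALSE)
  expect_equal(f2$rate, 5)
  expect_lte(fdr_per_hour(det, labels, starts, numeric(0))$rate, f2$rate)

  # detections inside the pre-onset tolerance are not false
  det <- rep(FALSE, 3600)
  det[1797] <- TRUE  # 4 s before an onset at 1800
  labels2 <- starts >= 1800 & starts < 1830
  expect_equal(fdr_per_hour(det, labels2, starts, 1800)$n_false, 0)
})

test_that("LOSO-CV scores every epoch once and never leaks the held block", {
  blocks <- tiny_blocks()$blocks
  scores <- loso_cv(blocks, "ll")
  expect_length(scores, length(blocks))
  for (b in seq_along(blocks)) {
    expect_equal(nrow(scores[[b]]), dim(blocks[[b]]$features)[1])
    ok <- !blocks[[b]]$artifact_mask
    expect_true(all(is.finite(scores[[b]][ok])))
    expect_true(all(is.na(scores[[b]][!ok])))
  }
  expect_error(loso_cv(blocks[1], "rf"), "at least 2")
})

test_that("a constant-scoring detector cannot beat chance", {
  blocks <- tiny_blocks()$blocks
  const <- lapply(blocks, function(b)
    matrix(1, dim(b$features)[1], dim(b$features)[2]))
  rep <- eval_report(blocks, const, threshold = 2, mode = "single")
  expect_equal(rep$auc, 0.5)
  expect_equal(rep$sensitivity, 0)
})

test_that("best channel is the AUC argmax with lowest-index ties", {
  expect_equal(best_channel(c(0.7, 0.9, 0.8)), 2)
  expect_equal(best_channel(0.6), 1)
  expect_equal(best_channel(c(0.9, 0.9)), 1)
})

test_that("fusion: max-score thresholding equals OR of detections", {
  expect_true(fuse_channels(matrix(c(FALSE, FALSE, TRUE, FALSE), 1),
                            "binary"))
  expect_false(fuse_channels(matrix(rep(FALSE, 4), 1), "binary"))
  set.seed(17)
  s <- matrix(rnorm(200), 50, 4)
  for (thr in c(-1, 0, 1)) {
    expect_equal(fuse_channels(s, "score") > thr,
                 apply(s > thr, 1, any))
  }
  expect_error(fuse_channels(matrix(nrow = 5, ncol = 0)), "at least one")
})
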