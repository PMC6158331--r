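# Random Forest detector (R interface over the compiled core).

#' Gini impurity decrease of a binary split
#'
#' `G(p) = 1 - sum_c p_c^2`; the decrease is the parent impurity minus the
#' child impurities weighted by their sample shares.
#'
#' @param parent_counts,left_counts,right_counts Two-element non-negative
#'   class-count vectors with `left + right == parent`.
#' @return Scalar impurity decrease.
#' @export
gini_impurity_decrease <- function(parent_counts, left_counts, right_counts) {
  if (any(c(parent_counts, left_counts, right_counts) < 0)) {
    stopf("counts must be non-negative")
  }
  if (!isTRUE(all.equal(left_counts + right_counts, parent_counts))) {
    stopf("left + right must equal parent")
  }
  n <- sum(parent_counts)
  if (n == 0) stopf("empty parent node")
  g <- function(cnt) {
    m <- sum(cnt)
    if (m == 0) return(0)
    1 - sum((cnt / m)^2)
  }
  g(parent_counts) - sum(left_counts) / n * g(left_counts) -
    sum(right_counts) / n * g(right_counts)
}

#' Default number of candidate features per node
#'
#' Ceiling of the square root of the feature count: 4 for the ten-feature
#' set.
#' @param n_features Number of features.
#' @export
rf_default_mtry <- function(n_features) as.integer(ceiling(sqrt(n_features)))

#' Train a Random Forest seizure classifier
#'
#' Bagged binary CART trees: each tree is grown on a bootstrap sample of the
#' training rows (about two thirds unique), each node split on the best of
#' `mtry` randomly drawn features by Gini impurity decrease, with candidate
#' thresholds at midpoints between consecutive distinct values. Growth stops
#' at purity or below `min_node` samples. The out-of-bag error is estimated
#' from each tree's held-out rows.
#'
#' @param x Numeric feature matrix, epochs x features.
#' @param y Logical or 0/1 labels (TRUE/1 = ictal).
#' @param n_trees Number of trees.
#' @param mtry Candidate features per node; defaults to
#'   `ceiling(sqrt(ncol(x)))`.
#' @param min_node Minimum node size eligible for splitting.
#' @param seed Integer seed; training is deterministic given it.
#' @param balanced Use class-balanced bootstrap samples (off by default,
#'   matching the plain bagging protocol).
#' @return An `rf_model` with `trees`, `oob_error`, and the call settings.
#' @export
rf_train <- function(x, y, n_trees = 100, mtry = rf_default_mtry(ncol(x)),
                     min_node = 5, seed = 1L, balanced = FALSE) {
  x <- as.matrix(x)
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) stopf("rf_train needs both classes present")
  fit <- .rf_train_cpp(x, y, as.integer(n_trees), as.integer(mtry),
                       as.integer(min_node), as.integer(seed), balanced)
  structure(list(trees = fit$trees, oob_error = fit$oob_error,
                 n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 min_node = as.integer(min_node), seed = as.integer(seed),
                 n_features = ncol(x),
                 feature_names = colnames(x) %||% feature_names()),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  nn <- sum(vapply(x$trees, function(t) length(t$feature), integer(1)))
  cat(sprintf("<rf_model> %d trees, mtry=%d, %d nodes, OOB error %.3f\n",
              x$n_trees, x$mtry, nn, x$oob_error))
  invisible(x)
}

#' Forest vote fraction per epoch
#'
#' Fraction of trees voting seizure; detection at `score > threshold`
#' (default 0.5, i.e. strict majority).
#'
#' @param model An `rf_model`.
#' @param x Feature matrix (or single feature vector).
#' @return Vote fractions in `[0, 1]`.
#' @export
rf_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  .rf_votes_cpp(model$trees, as.matrix(x))
}

#' Total node count of a forest
#' @param model An `rf_model`.
#' @export
rf_n_nodes <- function(model) {
  sum(vapply(model$trees, function(t) length(t$feature), integer(1)))
}
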