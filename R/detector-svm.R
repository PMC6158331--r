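# RBF-kernel soft-margin SVM with grid-searched hyperparameters.
#
# Features are z-scored with training-set statistics before anything else;
# the stats are stored in the model and reapplied at scoring time. The
# dual problem is solved by the compiled SMO core; the contract is the
# max-margin optimality of the decision function, not any particular
# solver schedule.

#' RBF kernel value
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)`.
#' @param x,y Numeric vectors of equal length.
#' @param gamma Kernel width parameter.
#' @export
rbf_kernel <- function(x, y, gamma) exp(-gamma * sum((x - y)^2))

#' Default hyperparameter grids
#'
#' Powers of four spanning the standard RBF search box:
#' `C = 2^(-5, -1, 3, 7, 11, 15)`, `gamma = 2^(-15, -11, -7, -3, 1)`.
#' @export
svm_default_grid <- function() {
  list(C = 2^seq(-5, 15, by = 4), gamma = 2^seq(-15, 1, by = 4))
}

# stratified k-fold assignment, deterministic under seed
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      id <- which(y == cls)
      fold[id] <- sample(rep_len(seq_len(k), length(id)))
    }
    fold
  })
}

svm_fit_raw <- function(x, y01, C, gamma, tol = 1e-3) {
  yy <- ifelse(y01 == 1, 1, -1)
  fit <- .svm_smo_cpp(x, yy, C, gamma, tol, 200L * nrow(x))
  list(sv = x[fit$sv_index, , drop = FALSE], coef = fit$coef, b = fit$b,
       iterations = fit$iterations)
}

#' Train an RBF-SVM seizure classifier with grid search
#'
#' Z-scores the features with training statistics, runs a stratified k-fold
#' cross-validated accuracy grid search over `(C, gamma)`, and refits on the
#' full training set at the best pair (ties broken toward smaller `C`, then
#' smaller `gamma`).
#'
#' @param x Numeric feature matrix, epochs x features.
#' @param y Logical or 0/1 labels (TRUE/1 = ictal).
#' @param c_grid,gamma_grid Hyperparameter candidates
#'   (see [svm_default_grid()]).
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @param max_train If the training set exceeds this many rows, it is
#'   stratified-downsampled (keeping all minority-class rows where
#'   possible) to bound the quadratic solver cost; `Inf` disables.
#' @return An `svm_model` with support vectors, dual coefficients, bias,
#'   chosen `C`/`gamma`, normalization stats, and the CV accuracy table.
#' @export
svm_train <- function(x, y, c_grid = svm_default_grid()$C,
                      gamma_grid = svm_default_grid()$gamma, folds = 5,
                      seed = 1L, max_train = 2000) {
  x <- as.matrix(x)
  y01 <- as.integer(as.logical(y))
  if (length(unique(y01)) < 2) stopf("svm_train needs both classes present")
  if (length(c_grid) < 1 || length(gamma_grid) < 1) stopf("empty grid")

  if (is.finite(max_train) && nrow(x) > max_train) {
    keep <- with_seed(derive_seed(seed, "subsample"), {
      pos <- which(y01 == 1)
      neg <- which(y01 == 0)
      n_pos <- min(length(pos), ceiling(max_train / 2))
      n_neg <- min(length(neg), max_train - n_pos)
      sort(c(sample(pos, n_pos), sample(neg, n_neg)))
    })
    x <- x[keep, , drop = FALSE]
    y01 <- y01[keep]
  }

  mu <- colMeans(x)
  sigma <- apply(x, 2, stats::sd)
  sigma[!is.finite(sigma) | sigma <= 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sigma, "/")

  fold <- stratified_folds(y01, folds, derive_seed(seed, "folds"))
  grid <- expand.grid(C = sort(c_grid), gamma = sort(gamma_grid))
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(y01[tr])) < 2 || !any(!tr)) next
      fit <- svm_fit_raw(xs[tr, , drop = FALSE], y01[tr],
                         grid$C[g], grid$gamma[g])
      dec <- .svm_decision_cpp(fit$sv, fit$coef, fit$b, grid$gamma[g],
                               xs[!tr, , drop = FALSE])
      correct <- correct + sum((dec > 0) == (y01[!tr] == 1))
    }
    acc[g] <- correct / length(y01)
  }
  best <- which.max(acc)  # grid sorted: ties -> smaller C, then gamma
  fit <- svm_fit_raw(xs, y01, grid$C[best], grid$gamma[best])
  structure(
    list(sv = fit$sv, coef = fit$coef, b = fit$b, C = grid$C[best],
         gamma = grid$gamma[best], mu = mu, sigma = sigma,
         cv_accuracy = cbind(grid, accuracy = acc),
         n_train = length(y01)),
    class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> %d SVs, C=%g, gamma=%g (CV acc %.3f on %d rows)\n",
              nrow(x$sv), x$C, x$gamma, max(x$cv_accuracy$accuracy),
              x$n_train))
  invisible(x)
}

#' SVM decision values
#'
#' Signed continuous decision value
#' `sum_i coef_i K(sv_i, x) + b` on inputs normalized with the model's
#' stored statistics. Detection at `value > 0` by default.
#'
#' @param model An `svm_model`.
#' @param x Feature matrix (or single feature vector) in raw feature units.
#' @return Numeric decision values.
#' @export
svm_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  xs <- sweep(sweep(as.matrix(x), 2, model$mu), 2, model$sigma, "/")
  .svm_decision_cpp(model$sv, model$coef, model$b, model$gamma, xs)
}

#' Save an SVM model as JSON
#' @param model An `svm_model`.
#' @param path Output path.
#' @export
svm_save_json <- function(model, path) {
  jsonlite::write_json(
    list(sv = model$sv, coef = model$coef, b = model$b, C = model$C,
         gamma = model$gamma, mu = model$mu, sigma = model$sigma),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an SVM model saved by [svm_save_json()]
#' @param path JSON path.
#' @export
svm_load_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sv = as.matrix(o$sv), coef = o$coef, b = o$b, C = o$C,
                 gamma = o$gamma, mu = o$mu, sigma = o$sigma,
                 cv_accuracy = data.frame(accuracy = NA_real_),
                 n_train = NA_integer_),
            class = "svm_model")
}
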