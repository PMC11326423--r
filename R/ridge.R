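# Ridge-regression baseline on flattened crops.
#
# Fitted in closed form through the dual (kernel) formulation, which is
# exact and fast when the voxel count far exceeds the sample count:
# with centred X (n x p) and an eigendecomposition X X' = U D U', the
# coefficients for any penalty lambda are X' U diag(1/(d + lambda)) U' y.
# The penalty is selected by nested cross-validation: inner folds score a
# fixed log-spaced grid, outer folds provide honest held-out predictions,
# and the final model is refit on all data with the penalty chosen by a
# full inner-style CV.

ridge_lambda_grid <- function() 10^seq(-3, 9, by = 1)

kfold_indices <- function(n, k) {
  split(sample.int(n), rep(seq_len(k), length.out = n))
}

# Exact ridge solutions for every lambda at once; returns the dual pieces
# needed for prediction without materializing p-length coefficients per fold.
ridge_dual_fit <- function(X, y, lambdas) {
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  K <- tcrossprod(Xc)
  eg <- eigen(K, symmetric = TRUE)
  Uty <- crossprod(eg$vectors, y - ybar)
  alphas <- lapply(lambdas, function(lam) {
    eg$vectors %*% (Uty / (pmax(eg$values, 0) + lam))
  })
  list(Xc = Xc, xbar = xbar, ybar = ybar, alphas = alphas)
}

ridge_dual_predict <- function(fit, lambda_index, Xnew) {
  Xn <- sweep(Xnew, 2L, fit$xbar)
  as.vector(Xn %*% crossprod(fit$Xc, fit$alphas[[lambda_index]])) + fit$ybar
}

# Mean inner-CV MSE per lambda on (X, y).
inner_cv_mse <- function(X, y, lambdas, inner) {
  folds <- kfold_indices(nrow(X), inner)
  err <- matrix(NA_real_, length(folds), length(lambdas))
  for (f in seq_along(folds)) {
    hold <- folds[[f]]
    fit <- ridge_dual_fit(X[-hold, , drop = FALSE], y[-hold], lambdas)
    for (j in seq_along(lambdas)) {
      pred <- ridge_dual_predict(fit, j, X[hold, , drop = FALSE])
      err[f, j] <- mean((pred - y[hold])^2)
    }
  }
  colMeans(err)
}

#' Ridge regression with nested cross-validation
#'
#' The penalty is chosen on a fixed log-spaced grid (`1e-3` to `1e9`) by
#' inner cross-validation; outer folds yield honest held-out predictions
#' for performance estimation; the final model is refit on all data with
#' the penalty selected by a full inner-style CV. All fold draws are
#' reproducible given `seed`.
#'
#' @param features Numeric matrix, one row per subject (flattened crops,
#'   see [flatten_crop()]), or the voxels-x-n matrix from
#'   [crops_to_matrix()] (auto-transposed).
#' @param labels Numeric criterion labels.
#' @param outer,inner Fold counts of the nested CV (defaults 5 and 6).
#' @param lambda_grid Candidate penalties.
#' @param seed Fold-assignment seed.
#' @param input_dims Optional crop extents, kept for saliency reshaping.
#' @return An `ihi_ridge`: `coef`, `intercept`, `lambda`, and
#'   `outer_predictions` (data frame `index, y, pred, fold, lambda`).
#' @export
ridge_nested_cv <- function(features, labels, outer = 5L, inner = 6L,
                            lambda_grid = ridge_lambda_grid(), seed = 1L,
                            input_dims = NULL) {
  X <- features
  if (!is.null(attr(X, "input_dims"))) {
    input_dims <- attr(X, "input_dims")
    X <- t(X) # crops_to_matrix layout is voxels x n
  }
  if (!is.matrix(X)) stop_input("`features` must be a matrix")
  n <- nrow(X)
  if (length(labels) != n) stop_input("labels must match the feature rows")
  if (stats::sd(labels) == 0) stop_input("labels are constant; ridge fit is degenerate")
  if (n < outer) stop_input("need at least `outer` samples")

  with_seed(seed, {
    outer_folds <- kfold_indices(n, outer)
    outer_pred <- data.frame(index = integer(), y = numeric(), pred = numeric(),
                             fold = integer(), lambda = numeric())
    for (f in seq_along(outer_folds)) {
      hold <- outer_folds[[f]]
      Xtr <- X[-hold, , drop = FALSE]
      ytr <- labels[-hold]
      mse <- inner_cv_mse(Xtr, ytr, lambda_grid, inner)
      j <- which.min(mse)
      fit <- ridge_dual_fit(Xtr, ytr, lambda_grid[j])
      pred <- ridge_dual_predict(fit, 1L, X[hold, , drop = FALSE])
      outer_pred <- rbind(outer_pred,
                          data.frame(index = hold, y = labels[hold], pred = pred,
                                     fold = f, lambda = lambda_grid[j]))
    }
    final_mse <- inner_cv_mse(X, labels, lambda_grid, inner)
    j <- which.min(final_mse)
    fit <- ridge_dual_fit(X, labels, lambda_grid[j])
    coef <- as.vector(crossprod(fit$Xc, fit$alphas[[1]]))
    structure(list(coef = coef,
                   intercept = fit$ybar - sum(fit$xbar * coef),
                   lambda = lambda_grid[j], lambda_grid = lambda_grid,
                   cv_mse = final_mse,
                   outer_predictions = outer_pred[order(outer_pred$index), ],
                   input_dims = input_dims, outer = outer, inner = inner,
                   seed = seed),
              class = "ihi_ridge")
  })
}

#' @export
print.ihi_ridge <- function(x, ...) {
  cat(sprintf("ridge regressor: p = %d, lambda = %g (nested CV %dx%d), outer-fold MSE %.4f\n",
              length(x$coef), x$lambda, x$outer, x$inner,
              mean((x$outer_predictions$pred - x$outer_predictions$y)^2)))
  invisible(x)
}
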