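# Epsilon-insensitive RBF support vector regression: direct fit, grid
# search, and BKA-optimized hyperparameters.

#' Fit an RBF support vector regression model
#'
#' Epsilon-insensitive SVR with the radial basis kernel
#' `K(x, z) = exp(-g * ||x - z||^2)`, solved by libsvm (via e1071) to
#' standard KKT optimality. Spectra are used as-is (no autoscaling): the RBF
#' kernel is translation-invariant, so column centering would not change the
#' model, and the absorbance scale is kept so that `g` is interpretable
#' across preprocessing methods.
#'
#' @param X numeric matrix of calibration spectra (samples in rows).
#' @param y numeric response (mass %).
#' @param c penalty (cost) coefficient, > 0.
#' @param g RBF kernel parameter, > 0.
#' @param epsilon width of the insensitivity tube (default 0.1).
#' @return an object of class `svr_model` wrapping the libsvm fit, with a
#'   `predict` method.
#' @export
fit_svr <- function(X, y, c, g, epsilon = 0.1) {
  if (!is.numeric(c) || c <= 0 || !is.numeric(g) || g <= 0 || epsilon < 0) {
    stop("require c > 0, g > 0, epsilon >= 0", call. = FALSE)
  }
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in the training data", call. = FALSE)
  }
  fit <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                    cost = c, gamma = g, epsilon = epsilon, scale = FALSE,
                    fitted = FALSE)
  structure(list(fit = fit, params = list(c = c, g = g, epsilon = epsilon)),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$fit$tot.nSV == 0L) {
    # degenerate fit (all residuals inside the tube): the libsvm decision
    # function reduces to its constant offset
    return(rep(-object$fit$rho, nrow(newdata)))
  }
  as.numeric(stats::predict(object$fit, newdata))
}

#' @export
print.svr_model <- function(x, ...) {
  cat("<svr_model> RBF eps-SVR, c = ", format(x$params$c),
      ", g = ", format(x$params$g), ", ", x$fit$tot.nSV,
      " support vectors\n", sep = "")
  invisible(x)
}

#' Grid search for SVR hyperparameters
#'
#' Exhaustive 5-fold cross-validation over a log2-spaced `(c, g)` grid in
#' half-power (`sqrt(2)`) steps, the conventional libsvm-style search. The
#' default grid `c = 2^(-2..10)`, `g = 2^(-12..2)` covers the optima this
#' kind of calibration typically lands on (e.g. `c = 2^1.5 = 2.8284`,
#' `c = 2^6 = 64`, `g = 2^-5.5 = 0.0221`). Ties are broken toward smaller
#' `c`, then smaller `g`.
#'
#' @param X,y calibration data.
#' @param c_grid,g_grid candidate values (default half-power-of-2 grids).
#' @param folds cross-validation folds (default 5).
#' @param epsilon SVR tube width (default 0.1).
#' @param seed fold-assignment seed.
#' @return list with `params` (list `c`, `g`, `epsilon`), `rmsecv`, and the
#'   full `grid` data.frame of evaluated combinations.
#' @export
grid_search_svr <- function(X, y,
                            c_grid = 2^seq(-2, 10, by = 0.5),
                            g_grid = 2^seq(-12, 2, by = 0.5),
                            folds = 5L, epsilon = 0.1, seed = 1L) {
  if (!length(c_grid) || !length(g_grid)) {
    stop("hyperparameter grid is empty", call. = FALSE)
  }
  X <- as.matrix(X)
  fold_of <- make_folds(nrow(X), folds, seed = seed)
  grid <- expand.grid(c = sort(c_grid), g = sort(g_grid),
                      KEEP.OUT.ATTRS = FALSE)
  grid$rmsecv <- vapply(seq_len(nrow(grid)), function(k) {
    cross_val_rmse(
      function(Xtr, ytr) fit_svr(Xtr, ytr, grid$c[k], grid$g[k], epsilon),
      X, y, fold_of = fold_of)
  }, numeric(1))
  ord <- order(grid$rmsecv, grid$c, grid$g)
  best <- grid[ord[1], ]
  list(params = list(c = best$c, g = best$g, epsilon = epsilon),
       rmsecv = best$rmsecv, grid = grid)
}
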