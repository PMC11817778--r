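# NIPALS partial least squares regression with cross-validated choice of
# the number of latent variables.

# Core NIPALS decomposition for a single response. X and y are mean-centered
# here (no variance scaling). Returns cumulative regression-coefficient
# vectors for 1..ncomp components, so one decomposition serves every
# candidate LV count.
pls_nipals <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  ncomp <- min(ncomp, p, n - 1L)
  W <- matrix(0, p, ncomp)   # weights
  P <- matrix(0, p, ncomp)   # X loadings
  Q <- numeric(ncomp)        # y loadings
  R <- matrix(0, p, ncomp)   # W (P'W)^-1, built recursively
  B <- matrix(0, p, ncomp)   # cumulative coefficients per LV count
  b <- numeric(p)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)[, 1]
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn < 1e-12) break   # rank exhausted
    w <- w / wn
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < 1e-24) break
    pv <- crossprod(Xc, t)[, 1] / tt
    q <- sum(t * yc) / tt
    Xc <- Xc - t %*% rbind(pv)
    yc <- yc - q * t
    r <- w
    if (a > 1L) {
      for (j in seq_len(a - 1L)) r <- r - sum(P[, j] * w) * R[, j]
    }
    W[, a] <- w; P[, a] <- pv; Q[a] <- q; R[, a] <- r
    b <- b + q * r
    B[, a] <- b
    a_used <- a
  }
  if (a_used == 0L) {
    stop("PLS failed: the response has no covariance with the predictors",
         call. = FALSE)
  }
  list(coefs = B[, seq_len(a_used), drop = FALSE],
       x_mean = x_mean, y_mean = y_mean,
       weights = W[, seq_len(a_used), drop = FALSE],
       loadings = P[, seq_len(a_used), drop = FALSE],
       y_loadings = Q[seq_len(a_used)],
       ncomp = a_used)
}

# Predictions for every LV count at once: n x ncomp matrix.
pls_predict_all <- function(fit, Xnew) {
  Xc <- sweep(as.matrix(Xnew), 2L, fit$x_mean)
  Xc %*% fit$coefs + fit$y_mean
}

#' Fit a PLSR calibration model
#'
#' NIPALS partial least squares on mean-centered predictors and response
#' (no variance scaling). The number of latent variables (LVs) is chosen by
#' k-fold cross-validation over `1:max_lvs` (the study searches 1-20 with
#' five folds), taking the smallest LV count at the minimum RMSECV. If the
#' predictor matrix runs out of rank before `max_lvs` components, the
#' candidate range is capped with a warning.
#'
#' @param X numeric matrix of calibration spectra (samples in rows).
#' @param y numeric response (mass %).
#' @param max_lvs maximum number of latent variables to consider (default 20).
#' @param folds number of cross-validation folds (default 5).
#' @param n_lvs optional fixed LV count; skips cross-validation.
#' @param seed seed for the fold assignment (default 1).
#' @return an object of class `plsr_model` with elements `n_lvs`, `b`
#'   (coefficient vector for the chosen LV count), `x_mean`, `y_mean`,
#'   `cv_curve` (RMSECV per candidate LV count; `NULL` when `n_lvs` is
#'   fixed), and the NIPALS factors.
#' @export
fit_plsr <- function(X, y, max_lvs = 20L, folds = 5L, n_lvs = NULL,
                     seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("`y` length must match rows of `X`", call. = FALSE)
  cv_curve <- NULL
  if (is.null(n_lvs)) {
    if (folds > n) stop("`folds` exceeds the number of samples", call. = FALSE)
    fold_of <- make_folds(n, folds, seed = seed)
    cap <- min(max_lvs, ncol(X), n - max(tabulate(fold_of)) - 1L)
    if (cap < 1L) stop("too few samples for cross-validated PLSR", call. = FALSE)
    press <- NULL
    used <- cap
    for (f in seq_len(folds)) {
      hold <- fold_of == f
      fit <- pls_nipals(X[!hold, , drop = FALSE], y[!hold], cap)
      used <- min(used, fit$ncomp)
      pred <- pls_predict_all(fit, X[hold, , drop = FALSE])
      if (is.null(press)) press <- numeric(cap)
      res2 <- (y[hold] - pred[, seq_len(fit$ncomp), drop = FALSE])^2
      # components beyond fit$ncomp (rank exhausted in this fold) reuse the
      # deepest available prediction
      full <- matrix(res2[, fit$ncomp], nrow(res2), cap)
      full[, seq_len(fit$ncomp)] <- res2
      press <- press + colSums(full)
    }
    cv_curve <- sqrt(press / n)
    if (used < cap) {
      warning("PLSR candidate LVs capped at ", used,
              " by the rank of the calibration data", call. = FALSE)
      cv_curve <- cv_curve[seq_len(used)]
    }
    n_lvs <- which.min(cv_curve)   # ties -> smaller LV count
  } else {
    n_lvs <- stopifnot_scalar_count(n_lvs, "n_lvs")
  }
  fit <- pls_nipals(X, y, n_lvs)
  n_lvs <- min(n_lvs, fit$ncomp)
  structure(
    list(n_lvs = n_lvs,
         b = fit$coefs[, n_lvs],
         x_mean = fit$x_mean, y_mean = fit$y_mean,
         weights = fit$weights, loadings = fit$loadings,
         y_loadings = fit$y_loadings,
         cv_curve = cv_curve),
    class = "plsr_model"
  )
}

#' Predict from a PLSR model
#' @param object a `plsr_model`.
#' @param newdata numeric matrix of spectra (samples in rows).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  Xc <- sweep(as.matrix(newdata), 2L, object$x_mean)
  as.numeric(Xc %*% object$b + object$y_mean)
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("<plsr_model> ", x$n_lvs, " latent variable(s), ",
      length(x$b), " predictors\n", sep = "")
  invisible(x)
}
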