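# Competitive Adaptive Reweighted Sampling (CARS) wavelength selection.
#
# Monte-Carlo "survival of the fittest" over the wavelength variables: each
# run fits a PLS model on a random subset of calibration samples, weights
# every retained wavelength by the magnitude of its regression coefficient,
# forces out the low-weight tail via an exponentially decreasing retention
# ratio (EDF), resamples the survivors in proportion to their weights (ARS),
# and scores the resulting subset by cross-validated RMSE. The subset with
# the lowest RMSECV across all runs is selected.

#' CARS configuration
#'
#' @param n_runs number of Monte-Carlo sampling runs (default 50).
#' @param mc_sample_ratio fraction of calibration samples drawn (without
#'   replacement) in each run (default 0.80).
#' @param cv_folds folds for the per-run RMSECV (default 5).
#' @param max_lvs cap on the internal PLS latent variables (default 10); the
#'   working LV count is chosen once by cross-validation on the full
#'   calibration set and held fixed across runs.
#' @param seed integer seed controlling all Monte-Carlo draws.
#' @return list of class `cars_config`.
#' @export
cars_config <- function(n_runs = 50L, mc_sample_ratio = 0.80,
                        cv_folds = 5L, max_lvs = 10L, seed = 1L) {
  n_runs <- stopifnot_scalar_count(n_runs, "n_runs")
  if (n_runs < 2L) stop("`n_runs` must be at least 2", call. = FALSE)
  if (!is.numeric(mc_sample_ratio) || mc_sample_ratio <= 0 ||
      mc_sample_ratio >= 1) {
    stop("`mc_sample_ratio` must lie strictly between 0 and 1", call. = FALSE)
  }
  cv_folds <- stopifnot_scalar_count(cv_folds, "cv_folds")
  if (cv_folds < 2L) stop("`cv_folds` must be at least 2", call. = FALSE)
  structure(list(n_runs = n_runs, mc_sample_ratio = mc_sample_ratio,
                 cv_folds = cv_folds,
                 max_lvs = stopifnot_scalar_count(max_lvs, "max_lvs"),
                 seed = seed),
            class = "cars_config")
}

#' Exponentially decreasing retention ratio (EDF)
#'
#' The fraction of the `p` wavelengths force-retained at run `i` of `N`:
#' `r_i = a * exp(-k * i)` with `a = (p/2)^(1/(N-1))` and
#' `k = log(p/2)/(N-1)`, so that run 1 keeps all `p` variables and run `N`
#' keeps exactly 2.
#'
#' @param i run index, `1 <= i <= N`.
#' @param N total number of runs (>= 2).
#' @param p total number of wavelength variables (>= 2).
#' @return retention fraction in (0, 1].
#' @export
edf_ratio <- function(i, N, p) {
  if (N < 2) stop("`N` must be at least 2", call. = FALSE)
  if (p < 2) stop("`p` must be at least 2", call. = FALSE)
  if (any(i < 1 | i > N)) stop("`i` must lie in [1, N]", call. = FALSE)
  a <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  a * exp(-k * i)
}

#' Run CARS wavelength selection
#'
#' @param x calibration spectra: a [spectra_set()] (with `target` naming the
#'   response column) or a numeric matrix (then pass `y`).
#' @param target response: `"fA"`, `"fB"` or `"fC"` for a `spectra_set`.
#' @param config a [cars_config()].
#' @param y numeric response vector when `x` is a bare matrix.
#' @return an object of class `cars_result`: list with `runs` (data.frame:
#'   `run`, `n_retained`, `K`, `rmsecv`), `retained_sets` (list of index
#'   vectors per run), `best_run`, `selected_indices`, `selected_fraction`,
#'   `n_lvs` (internal PLS LV count), and `selected_wavenumbers` when the
#'   input carries a grid.
#' @export
run_cars <- function(x, target = c("fA", "fB", "fC"), config = cars_config(),
                     y = NULL) {
  if (inherits(x, "spectra_set")) {
    target <- match.arg(target)
    y <- target_values(x, target)
    X <- x$absorbance
    wn <- x$wavenumbers
  } else {
    X <- as.matrix(x)
    wn <- NULL
    if (is.null(y)) stop("`y` is required for matrix input", call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 wavelength variables", call. = FALSE)
  if (n < config$cv_folds) {
    stop("fewer samples than cross-validation folds", call. = FALSE)
  }
  N <- config$n_runs
  m <- ceiling(config$mc_sample_ratio * n)

  with_seed(config$seed, {
    # internal LV count: chosen once on the full calibration set, held fixed
    nlv <- fit_plsr(X, y, max_lvs = config$max_lvs, folds = config$cv_folds,
                    seed = sample.int(2^31 - 1L, 1L))$n_lvs
    fold_of <- make_folds(n, config$cv_folds,
                          seed = sample.int(2^31 - 1L, 1L))
    retained <- seq_len(p)
    runs <- data.frame(run = seq_len(N), n_retained = NA_integer_,
                       K = NA_integer_, rmsecv = NA_real_)
    retained_sets <- vector("list", N)
    for (i in seq_len(N)) {
      rows <- sample.int(n, m)
      ncomp <- max(1L, min(nlv, length(retained), m - 1L))
      fit <- pls_nipals(X[rows, retained, drop = FALSE], y[rows], ncomp)
      b <- fit$coefs[, fit$ncomp]
      w <- abs(b)
      if (sum(w) <= 0) w <- rep(1, length(retained))
      w <- w / sum(w)
      # forced selection by the EDF schedule
      K <- max(2L, ceiling(edf_ratio(i, N, p) * p))
      K <- min(K, length(retained))
      ord <- order(-w, seq_along(retained))
      forced <- retained[ord[seq_len(K)]]
      w_forced <- w[ord[seq_len(K)]]
      # adaptive reweighted sampling: p weighted draws with replacement
      # from the forced survivors (p = total variable count, so the
      # distinct-survivor count tracks the EDF schedule); the distinct
      # draws form the new retained set
      draws <- forced[sample.int(K, p, replace = TRUE, prob = w_forced)]
      new_set <- sort(unique(draws))
      if (length(new_set) < 2L) {
        new_set <- sort(unique(c(new_set, forced[seq_len(2L)])))
      }
      retained <- new_set
      ncomp_cv <- max(1L, min(nlv, length(retained)))
      rmsecv <- cross_val_rmse(
        function(Xtr, ytr) {
          f <- pls_nipals(Xtr, ytr, ncomp_cv)
          structure(list(fit = f), class = "cars_pls")
        },
        X[, retained, drop = FALSE], y, fold_of = fold_of)
      if (!is.finite(rmsecv)) {
        stop("non-finite RMSECV at CARS run ", i, call. = FALSE)
      }
      runs$n_retained[i] <- length(retained)
      runs$K[i] <- K
      runs$rmsecv[i] <- rmsecv
      retained_sets[[i]] <- retained
    }
    # minimum RMSECV; ties -> fewer variables, then earlier run
    ord <- order(runs$rmsecv, runs$n_retained, runs$run)
    best <- ord[1]
    selected <- retained_sets[[best]]
    structure(
      list(runs = runs, retained_sets = retained_sets, best_run = best,
           selected_indices = selected,
           selected_fraction = length(selected) / p,
           n_lvs = nlv,
           selected_wavenumbers = if (!is.null(wn)) wn[selected] else NULL),
      class = "cars_result"
    )
  })
}

# minimal predict shim for the internal PLS fits used during CARS CV
#' @export
predict.cars_pls <- function(object, newdata, ...) {
  f <- object$fit
  pls_predict_all(f, newdata)[, f$ncomp]
}

#' @export
print.cars_result <- function(x, ...) {
  cat("<cars_result> best run ", x$best_run, ": ",
      length(x$selected_indices), " variables selected (",
      sprintf("%.1f%%", 100 * x$selected_fraction), "), RMSECV = ",
      format(x$runs$rmsecv[x$best_run], digits = 5), "\n", sep = "")
  invisible(x)
}
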