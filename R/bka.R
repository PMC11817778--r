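# Black-winged kite algorithm (BKA): a two-phase population metaheuristic
# (attacking = exploration around each kite's own position with an
# iteration-shrinking step, migration = Cauchy-perturbed moves relative to
# the population leader), with greedy selection after every move. Used here
# to tune the (c, g) hyperparameters of RBF-SVR in log2 space.

#' Black-winged kite optimization
#'
#' Minimizes `objective` over a box. Each iteration applies the attacking
#' phase (`x' = x + n (1 + sin(r)) x` with probability 0.9, else
#' `x' = x + n (2r - 1) x`, where `n = 0.05 exp(-2 (t/T)^2)` shrinks with
#' iteration) and the migration phase (`x' = x + Cauchy * (x - L)` when the
#' kite beats the leader `L`, else `x' = x + Cauchy * (L - m x)` with
#' `m = 2 sin(r + pi/2)`), keeping a move only when it improves the
#' objective. Candidates are clamped to the bounds; a candidate with a
#' non-finite objective is rejected. Objective evaluations are cached.
#'
#' @param objective function mapping a numeric vector (length =
#'   `length(lower)`) to a scalar to minimize.
#' @param lower,upper numeric bound vectors, `lower < upper`.
#' @param pop_size population size (>= 4, default 20).
#' @param max_iter number of iterations (default 20); `0` returns the best
#'   of the random initialization.
#' @param seed integer seed.
#' @return list with `par` (best position), `value` (best objective),
#'   `trace` (best-so-far value after initialization and each iteration;
#'   non-increasing), `n_evals` (distinct objective evaluations).
#' @export
#' @examples
#' res <- bka_optimize(function(u) sum(u^2), c(-5, -5), c(5, 5),
#'                     pop_size = 20, max_iter = 100, seed = 1)
#' res$value < 1e-2
bka_optimize <- function(objective, lower, upper, pop_size = 20L,
                         max_iter = 20L, seed = 1L) {
  d <- length(lower)
  if (length(upper) != d || any(lower >= upper)) {
    stop("`lower` and `upper` must be equal-length with lower < upper",
         call. = FALSE)
  }
  pop_size <- stopifnot_scalar_count(pop_size, "pop_size")
  if (pop_size < 4L) stop("`pop_size` must be at least 4", call. = FALSE)
  if (!is.numeric(max_iter) || max_iter < 0 || max_iter != round(max_iter)) {
    stop("`max_iter` must be a non-negative integer", call. = FALSE)
  }
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  f_eval <- function(x) {
    key <- paste(format(x, digits = 17), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- objective(x)
    v <- if (is.numeric(v) && length(v) == 1L && is.finite(v)) v else Inf
    n_evals <<- n_evals + 1L
    cache[[key]] <- v
    v
  }
  clamp <- function(x) pmin(pmax(x, lower), upper)
  with_seed(seed, {
    pos <- matrix(stats::runif(pop_size * d, rep(lower, each = pop_size),
                               rep(upper, each = pop_size)),
                  nrow = pop_size)
    fit <- apply(pos, 1L, f_eval)
    best_i <- which.min(fit)
    best_x <- pos[best_i, ]
    best_f <- fit[best_i]
    trace <- best_f
    T_ <- max(max_iter, 1L)
    for (t in seq_len(max_iter)) {
      n_step <- 0.05 * exp(-2 * (t / T_)^2)
      # leader snapshot for this iteration's comparisons
      lead_i <- which.min(fit)
      lead_x <- pos[lead_i, ]
      lead_f <- fit[lead_i]
      # attacking phase
      for (i in seq_len(pop_size)) {
        r <- stats::runif(1)
        cand <- if (0.9 < r) {
          pos[i, ] + n_step * (1 + sin(r)) * pos[i, ]
        } else {
          pos[i, ] + n_step * (2 * r - 1) * pos[i, ]
        }
        cand <- clamp(cand)
        fc <- f_eval(cand)
        if (fc < fit[i]) {
          pos[i, ] <- cand
          fit[i] <- fc
        }
      }
      # migration phase, relative to the iteration leader
      for (i in seq_len(pop_size)) {
        r <- stats::runif(1)
        m <- 2 * sin(r + pi / 2)
        cauchy <- stats::rcauchy(d)
        cand <- if (fit[i] < lead_f) {
          pos[i, ] + cauchy * (pos[i, ] - lead_x)
        } else {
          pos[i, ] + cauchy * (lead_x - m * pos[i, ])
        }
        cand <- clamp(cand)
        fc <- f_eval(cand)
        if (fc < fit[i]) {
          pos[i, ] <- cand
          fit[i] <- fc
        }
      }
      best_i <- which.min(fit)
      if (fit[best_i] < best_f) {
        best_f <- fit[best_i]
        best_x <- pos[best_i, ]
      }
      trace <- c(trace, best_f)
    }
    list(par = best_x, value = best_f, trace = trace, n_evals = n_evals)
  })
}

#' BKA-SVR configuration
#'
#' @param pop_size kite population (default 20).
#' @param max_iter iterations (default 20).
#' @param c_bounds search interval for the SVR penalty `c`
#'   (default `[0.01, 1024]`).
#' @param g_bounds search interval for the RBF parameter `g`
#'   (default `[1e-4, 1]`).
#' @param seed integer seed.
#' @return list of class `bka_config`.
#' @export
bka_config <- function(pop_size = 20L, max_iter = 20L,
                       c_bounds = c(0.01, 1024), g_bounds = c(1e-4, 1),
                       seed = 1L) {
  if (any(c(c_bounds, g_bounds) <= 0) ||
      c_bounds[1] >= c_bounds[2] || g_bounds[1] >= g_bounds[2]) {
    stop("bounds must be positive with lower < upper", call. = FALSE)
  }
  structure(list(pop_size = pop_size, max_iter = max_iter,
                 c_bounds = c_bounds, g_bounds = g_bounds, seed = seed),
            class = "bka_config")
}

#' Fit SVR with BKA-optimized hyperparameters
#'
#' Minimizes the k-fold RMSECV of [fit_svr()] over `(c, g)`, searching in
#' log2 space for scale invariance, then refits on the full calibration set
#' at the optimum. The fold assignment is fixed across all candidate
#' evaluations so RMSECVs are comparable.
#'
#' @param X,y calibration data.
#' @param config a [bka_config()].
#' @param folds cross-validation folds (default 5).
#' @param epsilon SVR tube width (default 0.1).
#' @return list with `model` (an `svr_model` refitted on all data), `params`
#'   (list `c`, `g`, `epsilon`), `rmsecv`, and the BKA `trace`.
#' @export
fit_bka_svr <- function(X, y, config = bka_config(), folds = 5L,
                        epsilon = 0.1) {
  X <- as.matrix(X)
  fold_of <- with_seed(config$seed,
                       make_folds(nrow(X), folds,
                                  seed = sample.int(2^31 - 1L, 1L)))
  objective <- function(u) {
    cross_val_rmse(
      function(Xtr, ytr) fit_svr(Xtr, ytr, 2^u[1], 2^u[2], epsilon),
      X, y, fold_of = fold_of)
  }
  opt <- bka_optimize(objective,
                      lower = log2(c(config$c_bounds[1], config$g_bounds[1])),
                      upper = log2(c(config$c_bounds[2], config$g_bounds[2])),
                      pop_size = config$pop_size, max_iter = config$max_iter,
                      seed = config$seed)
  c_opt <- 2^opt$par[1]
  g_opt <- 2^opt$par[2]
  list(model = fit_svr(X, y, c_opt, g_opt, epsilon),
       params = list(c = c_opt, g = g_opt, epsilon = epsilon),
       rmsecv = opt$value, trace = opt$trace)
}
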