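# RBF support vector regression, grid search, and the black-winged kite
# optimizer.

toy_svr_data <- function(n = 30, seed = 44) {
  set.seed(seed)
  x <- sort(runif(n, -2, 2))
  y <- sin(2 * x) + rnorm(n, sd = 0.05)
  list(X = matrix(x, ncol = 1), y = y)
}

test_that("constant response stays inside the epsilon tube", {
  X <- matrix(rnorm(40), 20, 2)
  fit <- fit_svr(X, rep(5, 20), c = 10, g = 0.5, epsilon = 0.1)
  expect_true(all(abs(predict(fit, X) - 5) <= 0.1 + 1e-8))
})

test_that("near-diagonal kernel limit interpolates the training data", {
  set.seed(44)
  x <- seq(-2, 2, length.out = 30)   # evenly spaced, so g >> 1/spacing^2
  d <- list(X = matrix(x, ncol = 1), y = sin(2 * x) + rnorm(30, sd = 0.05))
  fit <- fit_svr(d$X, d$y, c = 1e4, g = 1e4, epsilon = 0.05)
  # residuals sit on the tube boundary up to the solver's KKT tolerance
  expect_true(all(abs(predict(fit, d$X) - d$y) <= 0.05 + 1e-2))
})

test_that("SVR predictions agree with an independent solver", {
  skip_if_not_installed("kernlab")
  d <- toy_svr_data()
  mine <- fit_svr(d$X, d$y, c = 8, g = 2, epsilon = 0.1)
  ref <- kernlab::ksvm(d$X, d$y, type = "eps-svr",
                       kernel = "rbfdot", kpar = list(sigma = 2),
                       C = 8, epsilon = 0.1, scaled = FALSE, tol = 1e-6)
  expect_equal(predict(mine, d$X),
               as.numeric(kernlab::predict(ref, d$X)),
               tolerance = 1e-2)
})

test_that("SVR validates its hyperparameters and inputs", {
  d <- toy_svr_data()
  expect_error(fit_svr(d$X, d$y, c = -1, g = 1), "c > 0")
  expect_error(fit_svr(d$X, d$y, c = 1, g = 0), "g > 0")
  bad <- d$X
  bad[1] <- NaN
  expect_error(fit_svr(bad, d$y, c = 1, g = 1), "non-finite")
})

test_that("grid search returns the verified grid minimum", {
  d <- toy_svr_data()
  c_grid <- 2^seq(0, 4, by = 1)
  g_grid <- 2^seq(-3, 1, by = 1)
  gs <- grid_search_svr(d$X, d$y, c_grid, g_grid, folds = 5, seed = 21)
  # exhaustive re-evaluation oracle with the same fold map
  fold_of <- nirstarch:::make_folds(nrow(d$X), 5, seed = 21)
  redo <- vapply(seq_len(nrow(gs$grid)), function(k) {
    cross_val_rmse(
      function(Xtr, ytr) fit_svr(Xtr, ytr, gs$grid$c[k], gs$grid$g[k], 0.1),
      d$X, d$y, fold_of = fold_of)
  }, numeric(1))
  expect_equal(gs$rmsecv, min(redo), tolerance = 1e-12)
  best <- which(redo == min(redo))[1]
  expect_equal(gs$params$c, gs$grid$c[best])
  # degenerate one-point grid
  one <- grid_search_svr(d$X, d$y, c_grid = 2, g_grid = 0.5, folds = 5)
  expect_equal(one$params$c, 2)
  expect_equal(one$params$g, 0.5)
  expect_error(grid_search_svr(d$X, d$y, c_grid = numeric(0)), "empty")
})

test_that("default grid contains the half-power-of-2 optima", {
  gs_formals <- formals(grid_search_svr)
  c_grid <- eval(gs_formals$c_grid)
  g_grid <- eval(gs_formals$g_grid)
  for (cv in c(2.8284, 22.6274, 64)) {
    expect_true(any(abs(c_grid - cv) < 1e-3), label = paste("c =", cv))
  }
  expect_true(any(abs(g_grid - 0.0221) < 1e-3))
})

test_that("BKA minimizes the sphere function", {
  res <- bka_optimize(function(u) sum(u^2), lower = c(-5, -5),
                      upper = c(5, 5), pop_size = 20, max_iter = 100,
                      seed = 2)
  expect_lt(res$value, 1e-2)
  expect_true(all(diff(res$trace) <= 0))
  expect_length(res$trace, 101)
})

test_that("BKA keeps candidates inside the bounds", {
  seen <- new.env()
  seen$bad <- 0L
  obj <- function(u) {
    if (any(u < c(-1, 0) - 1e-12) || any(u > c(1, 3) + 1e-12)) {
      seen$bad <- seen$bad + 1L
    }
    (u[1] - 0.3)^2 + (u[2] - 2)^2
  }
  res <- bka_optimize(obj, c(-1, 0), c(1, 3), pop_size = 8, max_iter = 25,
                      seed = 5)
  expect_equal(seen$bad, 0L)
  expect_true(all(res$par >= c(-1, 0) & res$par <= c(1, 3)))
})

test_that("BKA degrades to best-of-initialization at zero iterations", {
  res <- bka_optimize(function(u) sum(u^2), c(-5, -5), c(5, 5),
                      pop_size = 10, max_iter = 0, seed = 3)
  expect_length(res$trace, 1)
  expect_true(is.finite(res$value))
})

test_that("BKA rejects NaN objectives gracefully", {
  obj <- function(u) if (u[1] > 0) NaN else sum(u^2)
  res <- bka_optimize(obj, c(-2, -2), c(2, 2), pop_size = 8, max_iter = 15,
                      seed = 9)
  expect_true(is.finite(res$value))
  expect_lte(res$par[1], 0)
})

test_that("BKA matches an exhaustive grid on a discretized SVR objective", {
  d <- toy_svr_data(n = 25, seed = 3)
  fold_of <- nirstarch:::make_folds(25, 5, seed = 8)
  objective <- function(u) {
    cross_val_rmse(
      function(Xtr, ytr) fit_svr(Xtr, ytr, 2^u[1], 2^u[2], 0.1),
      d$X, d$y, fold_of = fold_of)
  }
  lo <- c(-2, -4)
  hi <- c(6, 2)
  grid_pts <- expand.grid(u1 = seq(lo[1], hi[1], length.out = 20),
                          u2 = seq(lo[2], hi[2], length.out = 20))
  grid_best <- min(apply(grid_pts, 1, objective))
  res <- bka_optimize(objective, lo, hi, pop_size = 20, max_iter = 25,
                      seed = 6)
  expect_lte(res$value, grid_best)
})

test_that("BKA-SVR is deterministic and respects its bounds", {
  d <- toy_svr_data()
  cfg <- bka_config(pop_size = 8, max_iter = 8, seed = 31)
  a <- fit_bka_svr(d$X, d$y, cfg)
  b <- fit_bka_svr(d$X, d$y, cfg)
  expect_identical(a$params, b$params)
  expect_gte(a$params$c, cfg$c_bounds[1])
  expect_lte(a$params$c, cfg$c_bounds[2])
  expect_gte(a$params$g, cfg$g_bounds[1])
  expect_lte(a$params$g, cfg$g_bounds[2])
  expect_true(all(diff(a$trace) <= 0))
})
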