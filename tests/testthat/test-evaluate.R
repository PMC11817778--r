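# Metrics, cross-validation, and report assembly (incl. the leakage
# sentinel).

test_that("R^2 follows the sum-of-squares definition", {
  y <- c(1, 4, 2, 7, 5)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  set.seed(2)
  yt <- rnorm(40)
  yp <- yt + rnorm(40, sd = 0.5)
  oracle <- 1 - sum((yt - yp)^2) / sum((yt - mean(yt))^2)
  expect_equal(r_squared(yt, yp), oracle, tolerance = 1e-12)
  expect_error(r_squared(rep(1, 5), rnorm(5)), "constant")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("RMSE is the root mean squared residual and is homogeneous", {
  expect_equal(rmse(c(1, -1), c(0, 0)), 1)
  expect_equal(rmse(1:5, 1:5), 0)
  set.seed(4)
  yt <- rnorm(20)
  yp <- rnorm(20)
  expect_equal(rmse(3 * yt, 3 * yp), 3 * rmse(yt, yp), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("leave-one-out RMSECV matches the brute-force pooled formula", {
  set.seed(11)
  n <- 15
  X <- matrix(rnorm(n * 3), n, 3)
  y <- X %*% c(1, -1, 2) + rnorm(n, sd = 0.2)
  fit_fn <- function(Xtr, ytr) {
    structure(list(coef = coef(lm(ytr ~ Xtr))), class = "loo_lm")
  }
  assign("predict.loo_lm",
         function(object, newdata, ...) {
           as.numeric(cbind(1, newdata) %*% object$coef)
         },
         envir = globalenv())
  on.exit(rm("predict.loo_lm", envir = globalenv()), add = TRUE)
  got <- cross_val_rmse(fit_fn, X, y, folds = n, seed = 1)
  press <- vapply(seq_len(n), function(i) {
    fit <- lm(y[-i] ~ X[-i, , drop = FALSE])
    (y[i] - sum(c(1, X[i, ]) * coef(fit)))^2
  }, numeric(1))
  expect_equal(got, sqrt(sum(press) / n), tolerance = 1e-10)
})

test_that("cross-validation generalizes noiseless linear signal", {
  set.seed(6)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- as.numeric(X %*% c(2, -1, 0.5, 3))
  got <- cross_val_rmse(function(Xtr, ytr) fit_plsr(Xtr, ytr, n_lvs = 4),
                        X, y, folds = 5, seed = 3)
  expect_lt(got, 1e-8)
})

test_that("RMSECV is deterministic given the seed", {
  set.seed(9)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  fit_fn <- function(Xtr, ytr) fit_plsr(Xtr, ytr, n_lvs = 2)
  expect_identical(cross_val_rmse(fit_fn, X, y, folds = 5, seed = 42),
                   cross_val_rmse(fit_fn, X, y, folds = 5, seed = 42))
  expect_error(cross_val_rmse(fit_fn, X, y, folds = 40), "exceeds")
})

test_that("report rows keep calibration and prediction metrics separate", {
  # adversarial fixture: the model is perfect on the calibration rows and
  # useless on the prediction rows, so any leakage flips the metrics
  n <- 40
  X <- matrix(seq_len(n), ncol = 1)
  y <- numeric(n)
  train <- 1:20
  test <- 21:40
  y[train] <- X[train, 1]
  y[test] <- -X[test, 1]
  split <- structure(list(train_indices = train, test_indices = test,
                          n_train = 20, n_test = 20), class = "ks_split")
  model <- structure(list(), class = "identity_model")
  assign("predict.identity_model",
         function(object, newdata, ...) as.numeric(newdata[, 1]),
         envir = globalenv())
  on.exit(rm("predict.identity_model", envir = globalenv()), add = TRUE)
  row <- eval_model(model, X, y, split, "fA", "IDENT", params = "")
  expect_equal(row$RC2, 1)
  expect_equal(row$RMSEC, 0)
  expect_lt(row$RP2, 0)
  expect_gt(row$RMSEP, 10)
})

test_that("build_report stacks rows and keeps the table class", {
  r1 <- data.frame(target = "fA", model = "PLSR", params = "Lvs = 9",
                   RC2 = 0.99, RMSEC = 0.7, RP2 = 0.99, RMSEP = 0.8,
                   RMSECV = 0.9)
  rep2 <- build_report(r1, list(r1, r1))
  expect_s3_class(rep2, "report_table")
  expect_equal(nrow(rep2), 3)
})
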