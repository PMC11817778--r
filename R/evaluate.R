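# Calibration/prediction metrics and Table-style report assembly.

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. This is the
#' sum-of-squares definition (not squared Pearson correlation), so it can be
#' negative for models worse than the mean.
#'
#' @param y_true observed values.
#' @param y_pred predicted values.
#' @return scalar R^2.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (length(y_true) < 2L) stop("need at least 2 observations", call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0) {
    stop("R^2 is undefined for a constant `y_true`", call. = FALSE)
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Root mean square error
#'
#' `sqrt(mean((y - yhat)^2))`; in mass-% units when `y` is a mass
#' percentage (RMSEC on the calibration set, RMSEP on the prediction set).
#'
#' @param y_true observed values.
#' @param y_pred predicted values.
#' @return scalar RMSE (>= 0).
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (length(y_true) < 1L) stop("need at least 1 observation", call. = FALSE)
  sqrt(mean((y_true - y_pred)^2))
}

#' Cross-validated RMSE (RMSECV)
#'
#' k-fold cross-validation with pooled out-of-fold residuals:
#' `sqrt(sum_i (y_i - yhat_i^(-fold(i)))^2 / n)`. Folds are contiguous
#' blocks after a seeded shuffle, so the assignment is deterministic given
#' the seed and can be shared across models being compared.
#'
#' @param fit_fn function `(X_train, y_train) -> model`; predictions are
#'   obtained with `predict(model, X_test)`.
#' @param X numeric matrix (samples in rows).
#' @param y numeric response.
#' @param folds number of folds (default 5); `folds = n` is leave-one-out.
#' @param seed seed for the fold assignment.
#' @param fold_of optional precomputed fold map (overrides `folds`/`seed`).
#' @return scalar RMSECV.
#' @export
cross_val_rmse <- function(fit_fn, X, y, folds = 5L, seed = 1L,
                           fold_of = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(fold_of)) fold_of <- make_folds(n, folds, seed = seed)
  pred <- numeric(n)
  for (f in sort(unique(fold_of))) {
    hold <- fold_of == f
    model <- tryCatch(
      fit_fn(X[!hold, , drop = FALSE], y[!hold]),
      error = function(e) stop("fold ", f, " failed to fit: ",
                               conditionMessage(e), call. = FALSE)
    )
    pred[hold] <- as.numeric(predict(model, X[hold, , drop = FALSE]))
  }
  if (any(!is.finite(pred))) {
    stop("cross-validation produced non-finite predictions", call. = FALSE)
  }
  sqrt(sum((y - pred)^2) / n)
}

#' Evaluate one fitted model as a report row
#'
#' Computes the four headline metrics of the comparison tables: RC2/RMSEC on
#' the calibration samples only and RP2/RMSEP on the prediction samples
#' only. No prediction-set information enters the fit.
#'
#' @param model fitted model with a `predict` method over spectra matrices.
#' @param X full spectra matrix (calibration + prediction rows).
#' @param y full target vector.
#' @param split a [ks_split()] object.
#' @param target target label (e.g. `"fA"`).
#' @param model_label model name for the report (e.g. `"PLSR"`).
#' @param params parameter string as printed in the tables (e.g.
#'   `"Lvs = 11"` or `"c = 2.8284, g = 0.0221"`).
#' @param rmsecv optional cross-validated RMSE to record.
#' @return one-row data.frame of class `report_table`.
#' @export
eval_model <- function(model, X, y, split, target, model_label,
                       params = "", rmsecv = NA_real_) {
  tr <- split$train_indices
  te <- split$test_indices
  pred_tr <- as.numeric(predict(model, X[tr, , drop = FALSE]))
  row <- data.frame(
    target = target, model = model_label, params = params,
    RC2 = r_squared(y[tr], pred_tr),
    RMSEC = rmse(y[tr], pred_tr),
    RP2 = NA_real_, RMSEP = NA_real_,
    RMSECV = rmsecv,
    stringsAsFactors = FALSE
  )
  if (length(te)) {
    pred_te <- as.numeric(predict(model, X[te, , drop = FALSE]))
    row$RP2 <- r_squared(y[te], pred_te)
    row$RMSEP <- rmse(y[te], pred_te)
  }
  class(row) <- c("report_table", "data.frame")
  row
}

#' Assemble report rows into a report table
#'
#' @param ... one-row report tables from [eval_model()] (or lists thereof).
#' @return a `report_table` data.frame.
#' @export
build_report <- function(...) {
  args <- list(...)
  flat <- list()
  for (r in args) {
    if (is.data.frame(r)) flat[[length(flat) + 1L]] <- r
    else flat <- c(flat, r)
  }
  if (!length(flat)) stop("report is empty", call. = FALSE)
  rows <- do.call(rbind, flat)
  if (is.null(rows) || nrow(rows) == 0) {
    stop("report is empty", call. = FALSE)
  }
  rownames(rows) <- NULL
  class(rows) <- c("report_table", "data.frame")
  rows
}

#' @export
print.report_table <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) round(v, digits))
  print(y, row.names = FALSE)
  invisible(x)
}
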