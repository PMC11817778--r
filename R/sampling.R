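# Kennard-Stone calibration/prediction partitioning and the split-balance
# significance test.

#' Kennard-Stone calibration/prediction split
#'
#' Deterministic max-min-distance sample selection. The first two
#' calibration samples are the pair at maximum Euclidean distance in the
#' configured feature space (the spectra as given, raw or preprocessed);
#' each subsequent sample is the one whose minimum distance to the already
#' selected set is largest. Ties are broken by the lowest sample index.
#' The default study split takes 70% (rounded up) for calibration: 225
#' samples give 158 calibration and 67 prediction samples.
#'
#' @param x a [spectra_set()] or numeric matrix (samples in rows).
#' @param n_train number of calibration samples (at least 2); default
#'   `ceiling(train_frac * n)`.
#' @param train_frac calibration fraction used when `n_train` is `NULL`
#'   (default 0.7).
#' @return an object of class `ks_split`: list with `train_indices` (in
#'   selection order), `test_indices` (ascending), `n_train`, `n_test`.
#' @export
#' @examples
#' X <- matrix(0:9, ncol = 1)
#' ks_split(X, n_train = 2)$train_indices # the two extremes
ks_split <- function(x, n_train = NULL, train_frac = 0.7) {
  m <- as_abs_matrix(x)
  n <- nrow(m)
  if (is.null(n_train)) n_train <- ceiling(train_frac * n)
  n_train <- stopifnot_scalar_count(n_train, "n_train")
  if (n_train < 2L || n_train > n) {
    stop("`n_train` must be between 2 and the number of samples (", n, ")",
         call. = FALSE)
  }
  D <- as.matrix(stats::dist(m))
  # seed pair: maximum pairwise distance, ties -> lowest (i, j) row-major
  upper <- which(upper.tri(D), arr.ind = TRUE)
  upper <- upper[order(upper[, 1], upper[, 2]), , drop = FALSE]
  dvals <- D[upper]
  best <- upper[which.max(dvals), ]
  selected <- c(best[1], best[2])
  remaining <- setdiff(seq_len(n), selected)
  # min distance from each remaining sample to the selected set
  min_d <- pmin(D[remaining, selected[1]], D[remaining, selected[2]])
  while (length(selected) < n_train) {
    pick <- remaining[which.max(min_d)]   # which.max -> lowest index on ties
    selected <- c(selected, pick)
    keep <- remaining != pick
    remaining <- remaining[keep]
    min_d <- pmin(min_d[keep], D[remaining, pick])
  }
  structure(
    list(train_indices = as.integer(selected),
         test_indices = sort(remaining),
         n_train = length(selected),
         n_test = length(remaining)),
    class = "ks_split"
  )
}

#' @export
print.ks_split <- function(x, ...) {
  cat("<ks_split> ", x$n_train, " calibration / ", x$n_test,
      " prediction samples\n", sep = "")
  invisible(x)
}

#' Split-balance significance test
#'
#' Welch (unequal-variance) two-sample t-test comparing the target
#' distribution of the calibration and prediction sets, plus the boxplot
#' summary statistics used to display the split (median, quartiles,
#' whiskers, outliers by the Tukey 1.5 IQR rule). A p-value above 0.05
#' indicates no significant mean difference, i.e. a balanced split.
#'
#' @param y_train numeric target values of the calibration set.
#' @param y_test numeric target values of the prediction set.
#' @return list with `p_value`, `statistic`, `df`, and per-group boxplot
#'   summaries (`train`, `test`).
#' @export
balance_test <- function(y_train, y_test) {
  if (length(y_train) < 2L || length(y_test) < 2L) {
    stop("both groups need at least 2 values", call. = FALSE)
  }
  if (stats::var(y_train) + stats::var(y_test) <= 0) {
    stop("pooled variance is zero; the t-test is undefined", call. = FALSE)
  }
  tt <- stats::t.test(y_train, y_test, var.equal = FALSE)
  list(p_value = unname(tt$p.value),
       statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       train = box_summary(y_train),
       test = box_summary(y_test))
}

# Boxplot summary with quartiles (type-7) and Tukey 1.5*IQR whiskers.
box_summary <- function(y) {
  q <- stats::quantile(y, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- y[y >= lo & y <= hi]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(y[y < lo | y > hi]))
}
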