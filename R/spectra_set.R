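#' Construct a spectra set
#'
#' The universal data container passed between pipeline stages: a wavenumber
#' grid, an absorbance matrix (one row per sample) and the three regression
#' targets — sweet-potato starch mass percentage (`fA`), corn starch mass
#' percentage (`fB`) and total adulteration (`fC = fA + fB`).
#'
#' @param absorbance numeric matrix, `n_samples x n_points`, dimensionless
#'   absorbance. No missing values allowed.
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, strictly
#'   descending, one per column of `absorbance`.
#' @param targets data.frame with numeric columns `fA`, `fB`, `fC` (mass %),
#'   one row per sample; `fC` must equal `fA + fB`.
#' @param sample_ids character vector of unique sample labels; defaults to
#'   `"s0001"`, `"s0002"`, ...
#' @return an object of class `spectra_set` (a list with elements
#'   `wavenumbers`, `absorbance`, `targets`, `sample_ids`).
#' @export
#' @examples
#' grid <- make_wavenumber_grid(11)
#' abs_mat <- matrix(runif(22), nrow = 2)
#' tg <- data.frame(fA = c(1, 2), fB = c(3, 4), fC = c(4, 6))
#' spectra_set(abs_mat, grid, tg)
spectra_set <- function(absorbance, wavenumbers, targets,
                        sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  n <- nrow(absorbance)
  p <- ncol(absorbance)
  if (length(wavenumbers) != p) {
    stop("`wavenumbers` length (", length(wavenumbers),
         ") must match the number of absorbance columns (", p, ")",
         call. = FALSE)
  }
  if (p >= 2 && any(diff(wavenumbers) >= 0)) {
    stop("`wavenumbers` must be strictly descending", call. = FALSE)
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1, ]
    stop("non-finite absorbance at sample row ", bad[1],
         ", column ", bad[2], call. = FALSE)
  }
  targets <- as.data.frame(targets)
  need <- c("fA", "fB", "fC")
  missing_cols <- setdiff(need, names(targets))
  if (length(missing_cols)) {
    stop("`targets` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  targets <- targets[need]
  if (nrow(targets) != n) {
    stop("`targets` has ", nrow(targets), " rows but `absorbance` has ", n,
         call. = FALSE)
  }
  if (anyNA(targets)) stop("`targets` contains missing values", call. = FALSE)
  bad <- which(abs(targets$fC - (targets$fA + targets$fB)) > 1e-6)
  if (length(bad)) {
    stop("fC != fA + fB at sample row ", bad[1], call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%04d", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) {
    stop("`sample_ids` length must equal the number of samples", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("`sample_ids` must be unique", call. = FALSE)
  }
  rownames(absorbance) <- sample_ids
  rownames(targets) <- NULL
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         targets = targets, sample_ids = sample_ids),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " samples x ",
      length(x$wavenumbers), " wavenumbers (",
      format(max(x$wavenumbers)), " .. ", format(min(x$wavenumbers)),
      " cm^-1)\n", sep = "")
  if (nrow(x$targets) > 0) {
    cat("  total adulteration fC: ",
        paste(format(range(x$targets$fC)), collapse = " .. "), " %\n", sep = "")
  }
  invisible(x)
}

#' Number of samples in a spectra set
#' @param x a `spectra_set`.
#' @return integer sample count.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  nrow(x$absorbance)
}

#' Subset a spectra set by sample
#'
#' @param x a `spectra_set`.
#' @param i integer or logical index over samples.
#' @param j integer or logical index over wavenumber points (optional).
#' @param ... unused.
#' @return a `spectra_set` with the selected samples (and points).
#' @export
`[.spectra_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$absorbance))
  if (missing(j)) j <- seq_along(x$wavenumbers)
  spectra_set(x$absorbance[i, j, drop = FALSE],
              x$wavenumbers[j],
              x$targets[i, , drop = FALSE],
              x$sample_ids[i])
}

#' Extract one target column from a spectra set
#'
#' @param x a `spectra_set`.
#' @param target one of `"fA"` (sweet-potato starch %), `"fB"` (corn starch %),
#'   `"fC"` (total adulterant %).
#' @return numeric vector of target values in mass %.
#' @export
target_values <- function(x, target = c("fA", "fB", "fC")) {
  stopifnot(inherits(x, "spectra_set"))
  target <- match.arg(target)
  x$targets[[target]]
}

# Replace the absorbance matrix, keeping grid/targets/ids (internal).
set_absorbance <- function(x, absorbance) {
  spectra_set(absorbance, x$wavenumbers, x$targets, x$sample_ids)
}
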