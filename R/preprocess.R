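# Spectral preprocessing: standard normal variate, multiplicative scatter
# correction, Savitzky-Golay smoothing / differentiation.

# Accept either a spectra_set or a bare matrix; return the same shape.
as_abs_matrix <- function(x) {
  if (inherits(x, "spectra_set")) x$absorbance else as.matrix(x)
}
rewrap <- function(x, mat) {
  if (inherits(x, "spectra_set")) set_absorbance(x, mat) else mat
}

#' Standard normal variate (SNV) transform
#'
#' Each spectrum is centered and scaled to unit dispersion,
#' `x' = (x - mean(x)) / sd(x)` with the sample standard deviation
#' (denominator `n - 1`), removing per-sample offset and multiplicative
#' scatter effects. Every output row has mean 0 and sd 1.
#'
#' @param x a [spectra_set()] or numeric matrix (samples in rows).
#' @return object of the same type with transformed absorbance.
#' @export
snv <- function(x) {
  m <- as_abs_matrix(x)
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  degenerate <- which(s < .Machine$double.eps)
  if (length(degenerate)) {
    id <- if (inherits(x, "spectra_set")) x$sample_ids[degenerate[1]]
          else degenerate[1]
    stop("SNV undefined for constant spectrum (sample ", id, ")",
         call. = FALSE)
  }
  rewrap(x, (m - mu) / s)
}

#' Multiplicative scatter correction (MSC)
#'
#' Each spectrum is regressed on a reference spectrum by ordinary least
#' squares over all wavelengths, `x = a + b * reference`, and corrected as
#' `(x - a) / b`. The reference defaults to the mean spectrum of `x`; to
#' avoid information leakage when correcting prediction-set spectra, pass
#' the calibration-set reference explicitly (see [msc_reference()]).
#'
#' @param x a [spectra_set()] or numeric matrix (samples in rows).
#' @param reference `"mean"` (mean spectrum of `x`) or an explicit numeric
#'   reference spectrum on the same grid.
#' @return object of the same type with corrected absorbance; the reference
#'   used is attached as attribute `"msc_reference"`.
#' @export
msc <- function(x, reference = "mean") {
  m <- as_abs_matrix(x)
  ref <- if (is.character(reference) && identical(reference, "mean")) {
    colMeans(m)
  } else {
    as.numeric(reference)
  }
  if (length(ref) != ncol(m)) {
    stop("MSC reference length (", length(ref),
         ") does not match the spectral grid (", ncol(m), " points)",
         call. = FALSE)
  }
  if (stats::sd(ref) < .Machine$double.eps) {
    stop("MSC reference spectrum is constant; regression is ill-posed",
         call. = FALSE)
  }
  # closed-form per-row simple OLS against the common regressor
  ref_c <- ref - mean(ref)
  ss_ref <- sum(ref_c^2)
  b <- as.numeric(m %*% ref_c) / ss_ref
  a <- rowMeans(m) - b * mean(ref)
  tiny <- which(abs(b) < 1e-12)
  if (length(tiny)) {
    id <- if (inherits(x, "spectra_set")) x$sample_ids[tiny[1]] else tiny[1]
    stop("MSC cannot correct spectrum with near-zero slope (sample ",
         id, ")", call. = FALSE)
  }
  out <- (m - a) / b
  attr(out, "msc_reference") <- ref
  res <- rewrap(x, out)
  attr(res, "msc_reference") <- ref
  res
}

#' Mean reference spectrum for MSC
#'
#' Convenience helper: the column-mean spectrum of a calibration set, to be
#' reused when MSC-correcting prediction-set spectra.
#'
#' @param x a [spectra_set()] or numeric matrix.
#' @return numeric vector, one value per wavenumber.
#' @export
msc_reference <- function(x) colMeans(as_abs_matrix(x))

#' Savitzky-Golay smoothing and differentiation
#'
#' Moving-window local polynomial least squares. Each point is replaced by
#' the `deriv`-th derivative (with respect to wavenumber, so units are
#' absorbance per cm^-1 to the `deriv`) of the degree-`polyorder` polynomial
#' fitted to the surrounding `window` points, evaluated at that point. At
#' the spectrum edges the polynomial is fitted to the first (or last)
#' `window` points and evaluated at the edge positions, which avoids the
#' derivative artifacts that reflection padding fabricates at band edges.
#'
#' @param x a [spectra_set()] or numeric matrix (samples in rows), on an
#'   equally spaced wavenumber grid.
#' @param window odd window size, greater than `polyorder` (default 11).
#' @param polyorder polynomial degree (default 2).
#' @param deriv derivative order, `0 <= deriv <= polyorder` (default 0 =
#'   smoothing).
#' @param wavenumbers grid for a bare matrix input; taken from the
#'   `spectra_set` otherwise. Used only for the grid step, which scales
#'   derivatives into per-cm^-1 units.
#' @return object of the same type with filtered absorbance.
#' @export
sg_filter <- function(x, window = 11L, polyorder = 2L, deriv = 0L,
                      wavenumbers = NULL) {
  window <- stopifnot_scalar_count(window, "window")
  if (window %% 2L == 0L) {
    stop("`window` must be odd", call. = FALSE)
  }
  if (polyorder < 0 || polyorder != round(polyorder)) {
    stop("`polyorder` must be a non-negative integer", call. = FALSE)
  }
  if (window <= polyorder) {
    stop("`window` must exceed `polyorder`", call. = FALSE)
  }
  if (deriv < 0 || deriv > polyorder || deriv != round(deriv)) {
    stop("`deriv` must be an integer in [0, polyorder]", call. = FALSE)
  }
  m <- as_abs_matrix(x)
  p <- ncol(m)
  if (window >= p) {
    stop("`window` (", window, ") must be smaller than the number of points (",
         p, ")", call. = FALSE)
  }
  wn <- if (inherits(x, "spectra_set")) x$wavenumbers else wavenumbers
  h <- if (is.null(wn)) 1 else wn[2] - wn[1]   # signed physical step
  W <- sg_weights(window, polyorder, deriv, h)
  half <- (window - 1L) %/% 2L
  out <- matrix(0, nrow(m), p)
  # interior: one vectorized shift-and-add per window offset
  mid <- W$interior
  idx <- (half + 1L):(p - half)
  for (k in seq_len(window)) {
    out[, idx] <- out[, idx] + mid[k] * m[, idx + (k - half - 1L), drop = FALSE]
  }
  # edges: evaluate the first/last-window polynomial at the edge positions
  out[, 1:half] <- m[, 1:window, drop = FALSE] %*% t(W$head)
  out[, (p - half + 1L):p] <- m[, (p - window + 1L):p, drop = FALSE] %*% t(W$tail)
  rewrap(x, out)
}

# Projection weights for one window geometry: fit a degree-`polyorder`
# polynomial in physical offsets d = (j - center) * h, return the linear
# maps giving the deriv-th derivative at each in-window position.
sg_weights <- function(window, polyorder, deriv, h) {
  half <- (window - 1L) %/% 2L
  d <- (seq_len(window) - half - 1L) * h
  V <- outer(d, 0:polyorder, `^`)
  pinv <- solve(crossprod(V), t(V))          # (polyorder+1) x window
  # derivative evaluation row at offset delta:
  #   sum_{k >= deriv} beta_k * k!/(k-deriv)! * delta^(k-deriv)
  eval_rows <- matrix(0, window, polyorder + 1L)
  for (k in deriv:polyorder) {
    eval_rows[, k + 1L] <-
      factorial(k) / factorial(k - deriv) * d^(k - deriv)
  }
  A <- eval_rows %*% pinv                     # window x window
  list(interior = A[half + 1L, ],
       head = A[1:half, , drop = FALSE],
       tail = A[(half + 2L):window, , drop = FALSE])
}

#' Apply a named preprocessing method
#'
#' Dispatch helper used by the pipeline comparisons. Stateful methods (MSC)
#' are fitted on the calibration rows only and the fitted reference is used
#' to transform every spectrum.
#'
#' @param x a [spectra_set()].
#' @param method one of `"raw"`, `"snv"`, `"msc"`, `"sg"`.
#' @param calibration_rows row indices used to fit stateful transforms;
#'   defaults to all rows.
#' @param window,polyorder,deriv Savitzky-Golay settings for `method = "sg"`.
#' @return a preprocessed [spectra_set()].
#' @export
preprocess <- function(x, method = c("raw", "snv", "msc", "sg"),
                       calibration_rows = NULL,
                       window = 11L, polyorder = 2L, deriv = 0L) {
  method <- match.arg(method)
  switch(method,
    raw = x,
    snv = snv(x),
    msc = {
      ref <- if (is.null(calibration_rows)) msc_reference(x)
             else msc_reference(x[calibration_rows, ])
      msc(x, reference = ref)
    },
    sg = sg_filter(x, window = window, polyorder = polyorder, deriv = deriv)
  )
}
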