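# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so each file runs in seconds.

# a short grid + tiny design + low-noise spectra for fast end-to-end checks
tiny_spectra <- function(n_points = 120, replicates = 3, seed = 11,
                         endmembers = default_endmembers()) {
  simulate_spectra(build_design(replicates),
                   endmembers = endmembers,
                   grid = make_wavenumber_grid(n_points),
                   seed = seed)
}

# endmember model with every artifact turned off (exact linear mixing)
noiseless_endmembers <- function() {
  default_endmembers(gain_sd = 0, offset_sd = 0, slope_sd = 0, noise_sd = 0)
}

# random spectra_set with no mixture structure, for transform-level tests
random_spectra <- function(n = 8, p = 40, seed = 5) {
  set.seed(seed)
  tg <- data.frame(fA = runif(n, 0, 10), fB = runif(n, 0, 10))
  tg$fC <- tg$fA + tg$fB
  spectra_set(matrix(rnorm(n * p, mean = 1), n, p),
              make_wavenumber_grid(p), tg)
}

tmp_csv <- function() tempfile(fileext = ".csv")
tmp_dir <- function() {
  d <- tempfile()
  dir.create(d)
  d
}

# brute-force SG oracle: per-window polynomial fit with lm(), derivative of
# the fitted polynomial evaluated at the point of interest
sg_oracle <- function(x, wn, window, polyorder, deriv) {
  p <- length(x)
  half <- (window - 1) %/% 2
  out <- numeric(p)
  for (i in seq_len(p)) {
    lo <- max(1, min(i - half, p - window + 1))
    win <- lo:(lo + window - 1)
    d <- wn[win] - wn[i]
    fit <- lm(x[win] ~ poly(d, polyorder, raw = TRUE))
    beta <- coef(fit)
    out[i] <- sum(vapply(deriv:polyorder, function(k) {
      beta[k + 1] * factorial(k) / factorial(k - deriv) * 0^(k - deriv)
    }, numeric(1)))
  }
  out
}
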