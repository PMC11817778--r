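# SNV, MSC and Savitzky-Golay against closed-form and brute-force
# least-squares oracles.


test_that("SNV standardizes each spectrum to mean 0 and unit sd", {
  m <- rbind(c(1, 2, 3), c(5, 9, 1))
  out <- snv(m)
  expect_equal(out[1, ], c(-1, 0, 1))
  big <- random_spectra(n = 50, p = 200, seed = 2)
  z <- snv(big)$absorbance
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
})

test_that("SNV is idempotent and rejects constant spectra", {
  x <- random_spectra(n = 6, p = 30)
  once <- snv(x)$absorbance
  twice <- snv(snv(x))$absorbance
  expect_equal(twice, once, tolerance = 1e-10)
  m <- matrix(c(1, 1, 1, 2, 3, 4), 2, 3, byrow = TRUE)
  expect_error(snv(m), "constant spectrum")
})

test_that("MSC inverts affine scatter and matches the OLS oracle", {
  sp <- random_spectra(n = 50, p = 200, seed = 9)
  ref <- colMeans(sp$absorbance)
  # a row equal to the reference comes back unchanged
  m <- rbind(ref, 2 * ref + 5, sp$absorbance[1:3, ])
  out <- msc(m, reference = ref)
  expect_equal(out[1, ], ref, ignore_attr = TRUE)
  expect_equal(out[2, ], ref, ignore_attr = TRUE, tolerance = 1e-12)
  # per-row (a, b) against the normal-equations oracle
  corrected <- msc(sp$absorbance, reference = ref)
  for (i in c(1, 13, 50)) {
    ab <- coef(lm(sp$absorbance[i, ] ~ ref))
    oracle <- (sp$absorbance[i, ] - ab[1]) / ab[2]
    expect_equal(corrected[i, ], oracle, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("MSC maps the ensemble back onto its own mean spectrum", {
  # exact: a row equal to the reference is a fixed point
  sp <- random_spectra(n = 12, p = 25, seed = 4)
  ref <- msc_reference(sp)
  fixed <- msc(rbind(ref, sp$absorbance), reference = ref)
  expect_equal(fixed[1, ], ref, tolerance = 1e-12, ignore_attr = TRUE)
  # approximate: for gain/offset scatter around the reference, the
  # corrected mean stays on the reference (1/b nonlinearity is 2nd order)
  mix <- tiny_spectra(n_points = 80, replicates = 4, seed = 14)
  out <- msc(mix)
  rel <- max(abs(colMeans(out$absorbance) - msc_reference(mix))) /
    diff(range(msc_reference(mix)))
  expect_lt(rel, 0.01)
})

test_that("MSC rejects grid mismatch and degenerate references", {
  sp <- random_spectra(n = 4, p = 10)
  expect_error(msc(sp, reference = rep(1, 7)), "does not match")
  expect_error(msc(sp, reference = rep(2, 10)), "constant")
})

test_that("SG deriv 0 reproduces polynomials of the fitted degree exactly", {
  wn <- make_wavenumber_grid(60)
  quad <- 1e-7 * wn^2 - 3e-4 * wn + 0.5
  out <- sg_filter(rbind(quad), window = 11, polyorder = 2, deriv = 0,
                   wavenumbers = wn)
  expect_equal(out[1, ], quad, tolerance = 1e-9)
})

test_that("SG matches the brute-force windowed polyfit oracle", {
  set.seed(31)
  wn <- make_wavenumber_grid(200)
  m <- matrix(rnorm(50 * 200), 50, 200)
  for (cfg in list(list(w = 11, o = 2, d = 0), list(w = 11, o = 2, d = 2),
                   list(w = 7, o = 3, d = 1))) {
    out <- sg_filter(m, window = cfg$w, polyorder = cfg$o, deriv = cfg$d,
                     wavenumbers = wn)
    for (i in c(1, 25)) {
      expect_equal(out[i, ], sg_oracle(m[i, ], wn, cfg$w, cfg$o, cfg$d),
                   tolerance = 1e-10)
    }
  }
})

test_that("SG second derivative of a quadratic is the constant 2a", {
  wn <- make_wavenumber_grid(80)
  a <- 2.5e-7
  quad <- a * wn^2 - 1e-3 * wn + 2
  out <- sg_filter(rbind(quad), window = 11, polyorder = 2, deriv = 2,
                   wavenumbers = wn)
  expect_equal(out[1, ], rep(2 * a, 80), tolerance = 1e-12)
})

test_that("SG filtering is linear in its input", {
  set.seed(8)
  wn <- make_wavenumber_grid(40)
  x <- matrix(rnorm(40), 1)
  y <- matrix(rnorm(40), 1)
  lhs <- sg_filter(3 * x - 2 * y, window = 9, polyorder = 2,
                   wavenumbers = wn)
  rhs <- 3 * sg_filter(x, window = 9, polyorder = 2, wavenumbers = wn) -
    2 * sg_filter(y, window = 9, polyorder = 2, wavenumbers = wn)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("SG rejects invalid window configurations", {
  m <- matrix(rnorm(30), 1)
  expect_error(sg_filter(m, window = 8), "odd")
  expect_error(sg_filter(m, window = 3, polyorder = 3), "exceed")
  expect_error(sg_filter(m, window = 31), "smaller than the number")
  expect_error(sg_filter(m, window = 11, polyorder = 2, deriv = 3),
               "deriv")
})

test_that("SNV and MSC pull same-composition replicates together", {
  sp <- tiny_spectra(n_points = 100, replicates = 6, seed = 21)
  mean_rep_dist <- function(m) {
    lv <- round(sp$targets$fC, 6)
    mean(vapply(unique(lv), function(l) {
      rows <- which(lv == l)
      mean(dist(m[rows, , drop = FALSE]))
    }, numeric(1)))
  }
  raw_d <- mean_rep_dist(sp$absorbance)
  expect_lt(mean_rep_dist(snv(sp)$absorbance), raw_d)
  expect_lt(mean_rep_dist(msc(sp)$absorbance), raw_d)
})
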