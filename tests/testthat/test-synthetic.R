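# Wavenumber grid, mixture design, and the linear-mixing simulator.

test_that("wavenumber grid spans 10,000-4,000 descending with equal spacing", {
  expect_equal(make_wavenumber_grid(3), c(10000, 7000, 4000))
  g <- make_wavenumber_grid(1557)
  expect_length(g, 1557)
  expect_equal(g[1], 10000)
  expect_equal(g[1557], 4000)
  steps <- diff(g)
  expect_true(all(steps < 0))
  expect_equal(max(steps) - min(steps), 0, tolerance = 1e-9)
  expect_equal(g[1] - g[2], 6000 / 1556, tolerance = 1e-9)
  expect_error(make_wavenumber_grid(2), "at least 3")
  expect_error(make_wavenumber_grid(-1), "positive integer")
})

test_that("design expands levels x ratios into per-sample fractions", {
  d <- build_design()
  expect_s3_class(d, "mixture_design")
  expect_equal(nrow(d), 225)
  # ratio arithmetic: level 20 at ratio 3:2 by default; force 2:3 directly
  ra <- default_ratio_assignment()
  ra["20"] <- "2:3"
  d2 <- build_design(1, ratio_assignment = ra)
  row <- d2[d2$level == 20, ]
  expect_equal(row$fA, 8)
  expect_equal(row$fB, 12)
  expect_equal(row$fC, 20)
  # zero level is pure peanut skin
  zero <- d[d$level == 0, ]
  expect_true(all(zero$fA == 0 & zero$fB == 0 & zero$fC == 0))
  # fA + fB = fC exactly, everywhere
  expect_equal(d$fA + d$fB, d$fC)
  # the default assignment puts corn starch at 24% and 27% in the tail
  expect_equal(max(d$fB), 27)
  expect_setequal(unique(d$fB[d$fB > 15]), c(24, 27))
})

test_that("design rejects unknown ratios and bad replicate counts", {
  ra <- default_ratio_assignment()
  ra["20"] <- "5:7"
  expect_error(build_design(3, ratio_assignment = ra), "unknown ratio")
  expect_error(build_design(-2), "positive integer")
  expect_error(build_design(3, ratio_assignment = c("40" = "1:1")),
               "no ratio assigned")
})

test_that("noiseless simulation reproduces exact convex mixtures", {
  em <- noiseless_endmembers()
  grid <- make_wavenumber_grid(80)
  d <- build_design(2)
  sp <- simulate_spectra(d, em, grid, seed = 3)
  # pure peanut rows equal the peanut endmember exactly
  peanut <- endmember_spectrum(em$peanut_skin, grid)
  pure <- which(d$fC == 0)
  for (i in pure) expect_equal(unname(sp$absorbance[i, ]), peanut)
  # every row equals the direct three-term summation oracle
  A <- endmember_spectrum(em$sweet_potato_starch, grid)
  B <- endmember_spectrum(em$corn_starch, grid)
  for (i in seq_len(nrow(d))) {
    oracle <- (1 - d$fC[i] / 100) * peanut +
      d$fA[i] / 100 * A + d$fB[i] / 100 * B
    expect_equal(unname(sp$absorbance[i, ]), oracle, tolerance = 1e-12)
  }
})

test_that("noiseless absorbance is exactly linear in (fA, fB)", {
  sp <- tiny_spectra(n_points = 60, replicates = 2,
                     endmembers = noiseless_endmembers())
  fA <- sp$targets$fA
  fB <- sp$targets$fB
  for (j in c(1, 17, 60)) {
    fit <- lm(sp$absorbance[, j] ~ fA + fB)
    expect_lt(max(abs(residuals(fit))), 1e-10)
  }
})

test_that("component mass fractions sum to one for every sample", {
  d <- build_design(4)
  frac <- cbind(1 - d$fC / 100, d$fA / 100, d$fB / 100)
  expect_true(all(frac >= 0))
  expect_equal(rowSums(frac), rep(1, nrow(d)))
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  a <- tiny_spectra(seed = 7)
  b <- tiny_spectra(seed = 7)
  c <- tiny_spectra(seed = 8)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$absorbance, c$absorbance)))
})

test_that("simulator rejects out-of-range fractions and empty designs", {
  d <- build_design(1)
  d$fA[1] <- 120
  d$fC[1] <- d$fA[1] + d$fB[1]
  expect_error(
    simulate_spectra(d, grid = make_wavenumber_grid(10)),
    "\\[0, 100\\]")
  expect_error(
    simulate_spectra(d[0, ], grid = make_wavenumber_grid(10)),
    "non-empty")
})
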