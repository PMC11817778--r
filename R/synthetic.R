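# Synthetic FT-NIR mixture spectra: wavenumber grid, pure-component band
# models, the laboratory mixture design, and the linear-mixing simulator.

#' Make an equally spaced FT-NIR wavenumber grid
#'
#' The instrument range is 10,000 down to 4,000 cm^-1; the default grid
#' length elsewhere in the package is 1,557 points, consistent with an
#' 8 cm^-1-resolution FT-NIR export of that range.
#'
#' @param n_points number of grid points (at least 3).
#' @return numeric vector of wavenumbers, strictly descending from 10,000 to
#'   4,000 cm^-1 inclusive, equally spaced.
#' @export
#' @examples
#' make_wavenumber_grid(3) # 10000 7000 4000
make_wavenumber_grid <- function(n_points = 1557L) {
  n_points <- stopifnot_scalar_count(n_points, "n_points")
  if (n_points < 3L) {
    stop("`n_points` must be at least 3 to form a valid grid", call. = FALSE)
  }
  seq(10000, 4000, length.out = n_points)
}

#' Default pure-component band model
#'
#' Gaussian absorption-band tables for the three endmembers (peanut-skin
#' powder, sweet-potato starch, corn starch) plus the global scatter/noise
#' parameters used by [simulate_spectra()]. Band centers follow the
#' near-infrared assignments typical of these materials: peanut skin has its
#' cis-double-bond fatty-acid marker near 4,700 cm^-1, two strong C-H
#' overtone bands between 5,000 and 6,000 cm^-1 and a smooth, weak response
#' around 8,200-8,400 cm^-1; the two starches show simpler, more symmetric
#' O-H/C-H bands (sweet potato strongest near 4,300 and 6,850 cm^-1, corn
#' near 5,000-5,300 and 8,000 cm^-1). Band widths and heights are synthetic:
#' they are chosen to give plausible powder absorbance spectra, not measured
#' values for real materials.
#'
#' Scatter defaults: multiplicative gain sd 0.05, additive offset sd 0.01
#' absorbance, baseline slope sd 1e-6 per cm^-1, white-noise sd 0.002
#' absorbance.
#'
#' @param gain_sd sd of the per-sample multiplicative gain (around 1).
#' @param offset_sd sd of the per-sample additive offset (absorbance units).
#' @param slope_sd sd of the per-sample linear baseline slope (absorbance per
#'   cm^-1).
#' @param noise_sd sd of the per-point white Gaussian noise (absorbance units).
#' @return an object of class `endmember_model`: a list with one band table
#'   (data.frame `center`, `width`, `height`) per component and a `noise`
#'   list of scatter parameters.
#' @export
default_endmembers <- function(gain_sd = 0.05, offset_sd = 0.01,
                               slope_sd = 1e-6, noise_sd = 0.002) {
  band <- function(center, width, height) {
    data.frame(center = center, width = width, height = height)
  }
  em <- list(
    peanut_skin = band(
      center = c(4350, 4700, 5180, 5780, 6100, 6900, 8300, 5400),
      width  = c(  90,   70,  110,  130,  300,  180,  400, 2500),
      height = c(0.45, 0.80, 0.70, 0.60, 0.25, 0.30, 0.15, 0.35)),
    sweet_potato_starch = band(
      center = c(4300, 4750, 5200, 6300, 6850, 8350),
      width  = c(  80,   90,  120,  150,  160,  250),
      height = c(0.65, 0.35, 0.85, 0.30, 0.55, 0.08)),
    corn_starch = band(
      center = c(4400, 5000, 5280, 6900, 8000, 8400),
      width  = c(  85,  100,  110,  170,  220,  260),
      height = c(0.50, 0.60, 0.75, 0.40, 0.35, 0.10)),
    noise = list(gain_sd = gain_sd, offset_sd = offset_sd,
                 slope_sd = slope_sd, noise_sd = noise_sd)
  )
  validate_endmembers(em)
  class(em) <- "endmember_model"
  em
}

validate_endmembers <- function(em) {
  comps <- c("peanut_skin", "sweet_potato_starch", "corn_starch")
  for (comp in comps) {
    b <- em[[comp]]
    if (is.null(b) || !all(c("center", "width", "height") %in% names(b))) {
      stop("endmember model is missing band table for `", comp, "`",
           call. = FALSE)
    }
    if (any(b$height <= 0) || any(b$width <= 0)) {
      stop("band widths and heights must be positive (component `",
           comp, "`)", call. = FALSE)
    }
    if (any(b$center < 4000 | b$center > 10000)) {
      stop("band centers must lie within [4000, 10000] cm^-1 (component `",
           comp, "`)", call. = FALSE)
    }
  }
  nz <- em$noise
  if (is.null(nz) ||
      !all(c("gain_sd", "offset_sd", "slope_sd", "noise_sd") %in% names(nz)) ||
      any(unlist(nz[c("gain_sd", "offset_sd", "slope_sd", "noise_sd")]) < 0)) {
    stop("endmember model needs non-negative noise parameters ",
         "gain_sd, offset_sd, slope_sd, noise_sd", call. = FALSE)
  }
  invisible(em)
}

#' Evaluate a pure-component spectrum on a grid
#'
#' Sum of Gaussian bands: `sum_k height_k * exp(-0.5 ((nu - center_k)/width_k)^2)`.
#'
#' @param bands data.frame with columns `center`, `width`, `height`.
#' @param wavenumbers numeric grid in cm^-1.
#' @return numeric absorbance vector, one value per grid point.
#' @export
endmember_spectrum <- function(bands, wavenumbers) {
  out <- numeric(length(wavenumbers))
  for (k in seq_len(nrow(bands))) {
    out <- out + bands$height[k] *
      exp(-0.5 * ((wavenumbers - bands$center[k]) / bands$width[k])^2)
  }
  out
}

#' Default ratio-to-level assignment for the mixture design
#'
#' The study uses fifteen total-adulteration levels and five A:B
#' (sweet-potato : corn) ratios. The level-by-level assignment of ratios is
#' configurable; the default cycles the five ratios over the levels in
#' descending order but pins level 40% to ratio 2:3 and level 36% to ratio
#' 1:3, so corn starch reaches 24% and 27% — the long-tailed Adulterant-B
#' distribution whose high-level outliers appear in the split boxplots.
#'
#' @param levels numeric vector of total-adulteration levels (mass %).
#' @return named character vector mapping each nonzero level to a ratio
#'   string `"a:b"`.
#' @export
default_ratio_assignment <- function(levels = adulteration_levels()) {
  ratios <- c("1:1", "2:3", "3:2", "2:1", "1:3")
  pinned <- c("40" = "2:3", "36" = "1:3")
  nonzero <- levels[levels > 0]
  out <- character(length(nonzero))
  names(out) <- as.character(nonzero)
  free <- setdiff(names(out), names(pinned))
  out[names(pinned)[names(pinned) %in% names(out)]] <-
    pinned[names(pinned) %in% names(out)]
  out[free] <- rep(ratios, length.out = length(free))
  out
}

#' The fifteen total-adulteration levels (mass %)
#' @return numeric vector of levels, descending.
#' @export
adulteration_levels <- function() {
  c(40, 36, 30, 24, 20, 16, 12, 8, 6, 4, 3, 2, 1, 0.5, 0)
}

#' Build the mixture design table
#'
#' Expands levels x replicates into per-sample target fractions. For a level
#' `fC` with ratio `a:b`, the sweet-potato fraction is `fA = fC * a/(a+b)`
#' and the corn fraction `fB = fC * b/(a+b)`; level 0 is pure peanut skin.
#' The default design (15 levels x 15 replicates) has 225 samples.
#'
#' @param replicates_per_level replicate count per level (default 15).
#' @param ratio_assignment named character vector mapping nonzero levels to
#'   ratio strings from `{"1:1","2:3","3:2","2:1","1:3"}`; see
#'   [default_ratio_assignment()].
#' @param levels total-adulteration levels in mass %.
#' @return an object of class `mixture_design`: a data.frame with columns
#'   `level`, `ratio`, `replicate`, `fA`, `fB`, `fC`.
#' @export
#' @examples
#' d <- build_design()
#' nrow(d) # 225
build_design <- function(replicates_per_level = 15L,
                         ratio_assignment = default_ratio_assignment(levels),
                         levels = adulteration_levels()) {
  replicates_per_level <- stopifnot_scalar_count(replicates_per_level,
                                                 "replicates_per_level")
  allowed <- c("1:1", "2:3", "3:2", "2:1", "1:3")
  nonzero <- levels[levels > 0]
  missing_lv <- setdiff(as.character(nonzero), names(ratio_assignment))
  if (length(missing_lv)) {
    stop("no ratio assigned to level(s): ",
         paste(missing_lv, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(ratio_assignment[as.character(nonzero)], allowed)
  if (length(bad)) {
    stop("unknown ratio(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  rows <- lapply(levels, function(lv) {
    if (lv > 0) {
      ratio <- ratio_assignment[[as.character(lv)]]
      ab <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
      fA <- lv * ab[1] / sum(ab)
    } else {
      ratio <- NA_character_
      fA <- 0
    }
    data.frame(level = lv, ratio = ratio,
               replicate = seq_len(replicates_per_level),
               fA = fA, fB = lv - fA, fC = lv)
  })
  design <- do.call(rbind, rows)
  rownames(design) <- NULL
  class(design) <- c("mixture_design", "data.frame")
  design
}

#' Simulate FT-NIR mixture spectra
#'
#' Linear (Beer-Lambert-like) mixing of the three pure-component spectra,
#' followed by the measurement artifacts that scatter-correction
#' preprocessing is designed to remove. For a sample with mass fractions
#' `(fA, fB)` in percent, the ideal spectrum is
#' `s(nu) = (1 - fC/100) * peanut(nu) + fA/100 * sweet_potato(nu) + fB/100 * corn(nu)`
#' and the observed spectrum is
#' `gain * s(nu) + offset + slope * (nu - mean(nu)) + eps(nu)`,
#' with `gain ~ N(1, gain_sd^2)`, `offset ~ N(0, offset_sd^2)` and
#' `slope ~ N(0, slope_sd^2)` drawn per sample and `eps` white Gaussian
#' noise per point.
#'
#' @param design a `mixture_design` from [build_design()].
#' @param endmembers an `endmember_model`; see [default_endmembers()].
#' @param grid wavenumber grid from [make_wavenumber_grid()].
#' @param seed integer seed; the same seed reproduces the spectra exactly.
#' @return a [spectra_set()] with ground-truth targets attached.
#' @export
#' @examples
#' sp <- simulate_spectra(build_design(3), grid = make_wavenumber_grid(101),
#'                        seed = 1)
#' sp
simulate_spectra <- function(design,
                             endmembers = default_endmembers(),
                             grid = make_wavenumber_grid(),
                             seed = 1L) {
  if (!is.data.frame(design) || nrow(design) == 0) {
    stop("`design` must be a non-empty mixture design", call. = FALSE)
  }
  validate_endmembers(unclass(endmembers))
  if (any(design$fA < 0 | design$fB < 0 |
          design$fA > 100 | design$fB > 100 | design$fC > 100)) {
    stop("mass fractions must lie in [0, 100] percent", call. = FALSE)
  }
  n <- nrow(design)
  p <- length(grid)
  E <- rbind(
    peanut_skin         = endmember_spectrum(endmembers$peanut_skin, grid),
    sweet_potato_starch = endmember_spectrum(endmembers$sweet_potato_starch, grid),
    corn_starch         = endmember_spectrum(endmembers$corn_starch, grid)
  )
  M <- cbind(1 - design$fC / 100, design$fA / 100, design$fB / 100)
  ideal <- M %*% E
  nz <- endmembers$noise
  nu_centered <- grid - mean(grid)
  obs <- with_seed(seed, {
    gain <- 1 + stats::rnorm(n, 0, nz$gain_sd)
    offset <- stats::rnorm(n, 0, nz$offset_sd)
    slope <- stats::rnorm(n, 0, nz$slope_sd)
    eps <- matrix(stats::rnorm(n * p, 0, nz$noise_sd), nrow = n)
    gain * ideal + offset + outer(slope, nu_centered) + eps
  })
  ids <- sprintf("L%05.1f_r%02d", design$level, design$replicate)
  ids <- gsub(" ", "0", ids, fixed = TRUE)
  if (anyDuplicated(ids)) ids <- sprintf("s%04d", seq_len(n))
  spectra_set(obs, grid, design[c("fA", "fB", "fC")], ids)
}
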