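Package: nirstarch
Title: Chemometric Quantification of Starch Adulterants in Peanut-Skin
    Powder from FT-NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate calibration pipeline for quantifying sweet-potato
    and corn starch adulteration of peanut-skin powder from Fourier-transform
    near-infrared (FT-NIR) spectra. Provides a synthetic mixture-spectra
    generator (Gaussian-band endmembers, linear mixing, scatter/baseline/noise
    artifacts), spectral preprocessing (SNV, MSC, Savitzky-Golay
    smoothing/derivatives), Kennard-Stone sample partitioning, competitive
    adaptive reweighted sampling (CARS) wavelength selection, and calibration
    by NIPALS partial least squares regression, grid-searched RBF support
    vector regression, and black-winged kite algorithm (BKA) optimized
    support vector regression, with calibration/prediction metrics and
    report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
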