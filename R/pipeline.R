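# End-to-end orchestration of the two comparison experiments:
#  (1) preprocessing comparison — raw / SNV / MSC / SG, PLSR per target;
#  (2) model comparison — SG -> Kennard-Stone -> CARS per target ->
#      PLSR / grid-SVR / BKA-SVR on the selected wavelengths.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end experiments with the study's
#' defaults: 1,557-point grid over 10,000-4,000 cm^-1, 15 levels x 15
#' replicates (225 samples), SG window 11 / order 2, 70% Kennard-Stone
#' calibration fraction, PLSR latent variables searched over 1-20 with
#' 5-fold cross-validation, CARS with 50 Monte-Carlo runs, and SVR tuned by
#' half-power-of-2 grid search or BKA.
#'
#' @param seed global seed; every stochastic stage derives its own seed
#'   from it.
#' @param n_points wavenumber grid length.
#' @param replicates_per_level mixture-design replicates per level.
#' @param endmembers an `endmember_model` (bands + noise parameters).
#' @param preprocess_methods methods compared in experiment (1).
#' @param targets response columns to model.
#' @param train_frac Kennard-Stone calibration fraction.
#' @param sg_window,sg_polyorder,sg_deriv Savitzky-Golay settings.
#' @param max_lvs,cv_folds PLSR search range and fold count.
#' @param cars a [cars_config()] (its seed is overridden from `seed`).
#' @param bka a [bka_config()] (its seed is overridden from `seed`).
#' @param epsilon SVR tube width.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_points = 1557L,
                            replicates_per_level = 15L,
                            endmembers = default_endmembers(),
                            preprocess_methods = c("raw", "snv", "msc", "sg"),
                            targets = c("fA", "fB", "fC"),
                            train_frac = 0.7,
                            sg_window = 11L, sg_polyorder = 2L, sg_deriv = 0L,
                            max_lvs = 20L, cv_folds = 5L,
                            cars = cars_config(),
                            bka = bka_config(),
                            epsilon = 0.1) {
  if (is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(list(seed = as.integer(seed), n_points = n_points,
                 replicates_per_level = replicates_per_level,
                 endmembers = endmembers,
                 preprocess_methods = preprocess_methods, targets = targets,
                 train_frac = train_frac, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, sg_deriv = sg_deriv,
                 max_lvs = max_lvs, cv_folds = cv_folds,
                 cars = cars, bka = bka, epsilon = epsilon),
            class = "pipeline_config")
}

# stage seeds derived deterministically from the global seed
stage_seeds <- function(seed) {
  with_seed(seed, {
    s <- sample.int(2^31 - 2L, 6L)
    names(s) <- c("simulate", "plsr", "cars", "grid", "bka", "folds")
    s
  })
}

#' Simulate the study data set from a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return a [spectra_set()] (default: 225 samples x 1,557 points).
#' @export
simulate_study <- function(config = pipeline_config()) {
  seeds <- stage_seeds(config$seed)
  simulate_spectra(
    build_design(config$replicates_per_level),
    endmembers = config$endmembers,
    grid = make_wavenumber_grid(config$n_points),
    seed = seeds[["simulate"]]
  )
}

#' Preprocessing comparison experiment
#'
#' For each target and each preprocessing method, preprocesses the spectra
#' (stateful transforms fitted on the calibration rows only), splits by
#' Kennard-Stone on the preprocessed spectra, fits PLSR with
#' cross-validated latent variables, and reports RC2/RMSEC/RP2/RMSEP — a
#' 3-target x 4-method table.
#'
#' @param config a [pipeline_config()].
#' @param spectra optional precomputed [spectra_set()]; simulated from
#'   `config` when omitted.
#' @param verbose print one line per stage (default FALSE).
#' @return a `report_table` with `length(targets) * length(methods)` rows.
#' @export
run_preprocessing_comparison <- function(config = pipeline_config(),
                                         spectra = NULL, verbose = FALSE) {
  seeds <- stage_seeds(config$seed)
  if (is.null(spectra)) spectra <- simulate_study(config)
  rows <- list()
  for (method in config$preprocess_methods) {
    if (method == "msc") {
      # MSC is stateful: split on the uncorrected spectra (KS is
      # unsupervised), fit the reference on the calibration rows only,
      # then correct every spectrum with that reference
      split <- ks_split(spectra, train_frac = config$train_frac)
      ref <- msc_reference(spectra[split$train_indices, ])
      pp <- msc(spectra, reference = ref)
    } else {
      pp <- preprocess(spectra, method, window = config$sg_window,
                       polyorder = config$sg_polyorder,
                       deriv = config$sg_deriv)
      split <- ks_split(pp, train_frac = config$train_frac)
    }
    X <- pp$absorbance
    for (target in config$targets) {
      y <- target_values(pp, target)
      tr <- split$train_indices
      t0 <- proc.time()[3]
      model <- fit_plsr(X[tr, , drop = FALSE], y[tr],
                        max_lvs = config$max_lvs, folds = config$cv_folds,
                        seed = seeds[["plsr"]])
      row <- eval_model(model, X, y, split, target,
                        model_label = toupper(method),
                        params = sprintf("Lvs = %d", model$n_lvs),
                        rmsecv = min(model$cv_curve))
      rows[[length(rows) + 1L]] <- row
      if (verbose) {
        message(sprintf(
          "[preprocess %s | %s] Lvs=%d RP2=%.4f RMSEP=%.4f (%.1fs)",
          method, target, model$n_lvs, row$RP2, row$RMSEP,
          proc.time()[3] - t0))
      }
    }
  }
  build_report(rows)
}

#' Model comparison experiment
#'
#' The full pipeline: SG smoothing, Kennard-Stone split, CARS wavelength
#' selection per target on the calibration set, then PLSR, grid-searched
#' RBF-SVR and BKA-optimized RBF-SVR on the selected wavelengths — a
#' 3-target x 3-model table with the fitted parameters recorded per row.
#'
#' @inheritParams run_preprocessing_comparison
#' @return list with `report` (a `report_table`), `cars` (per-target
#'   `cars_result`), `split` (the [ks_split()]), and `spectra` (the
#'   SG-preprocessed set).
#' @export
run_model_comparison <- function(config = pipeline_config(), spectra = NULL,
                                 verbose = FALSE) {
  seeds <- stage_seeds(config$seed)
  if (is.null(spectra)) spectra <- simulate_study(config)
  pp <- preprocess(spectra, "sg", window = config$sg_window,
                   polyorder = config$sg_polyorder, deriv = config$sg_deriv)
  split <- ks_split(pp, train_frac = config$train_frac)
  tr <- split$train_indices
  rows <- list()
  cars_out <- list()
  for (target in config$targets) {
    y <- target_values(pp, target)
    t0 <- proc.time()[3]
    cfg_cars <- config$cars
    cfg_cars$seed <- seeds[["cars"]]
    sel <- run_cars(pp[tr, ], target, cfg_cars)
    cars_out[[target]] <- sel
    vars <- sel$selected_indices
    if (verbose) {
      message(sprintf("[cars | %s] %d variables (%.1f%%) in %.1fs", target,
                      length(vars), 100 * sel$selected_fraction,
                      proc.time()[3] - t0))
    }
    Xsel <- pp$absorbance[, vars, drop = FALSE]
    ytr <- y[tr]
    Xtr <- Xsel[tr, , drop = FALSE]

    t0 <- proc.time()[3]
    plsr <- fit_plsr(Xtr, ytr, max_lvs = config$max_lvs,
                     folds = config$cv_folds, seed = seeds[["plsr"]])
    rows[[length(rows) + 1L]] <- eval_model(
      plsr, Xsel, y, split, target, "PLSR",
      params = sprintf("Lvs = %d", plsr$n_lvs),
      rmsecv = min(plsr$cv_curve))
    if (verbose) message(sprintf("[plsr | %s] Lvs=%d (%.1fs)", target,
                                 plsr$n_lvs, proc.time()[3] - t0))

    t0 <- proc.time()[3]
    gs <- grid_search_svr(Xtr, ytr, folds = config$cv_folds,
                          epsilon = config$epsilon, seed = seeds[["grid"]])
    svr <- fit_svr(Xtr, ytr, gs$params$c, gs$params$g, config$epsilon)
    rows[[length(rows) + 1L]] <- eval_model(
      svr, Xsel, y, split, target, "SVM",
      params = sprintf("c = %.4f, g = %.4f", gs$params$c, gs$params$g),
      rmsecv = gs$rmsecv)
    if (verbose) message(sprintf("[svm | %s] c=%.4f g=%.4f (%.1fs)", target,
                                 gs$params$c, gs$params$g,
                                 proc.time()[3] - t0))

    t0 <- proc.time()[3]
    cfg_bka <- config$bka
    cfg_bka$seed <- seeds[["bka"]]
    bka <- fit_bka_svr(Xtr, ytr, cfg_bka, folds = config$cv_folds,
                       epsilon = config$epsilon)
    rows[[length(rows) + 1L]] <- eval_model(
      bka$model, Xsel, y, split, target, "BKA-SVM",
      params = sprintf("c = %.4f, g = %.4f", bka$params$c, bka$params$g),
      rmsecv = bka$rmsecv)
    if (verbose) message(sprintf("[bka-svm | %s] c=%.4f g=%.4f (%.1fs)",
                                 target, bka$params$c, bka$params$g,
                                 proc.time()[3] - t0))
  }
  list(report = build_report(rows), cars = cars_out, split = split,
       spectra = pp)
}

#' Run the full pipeline and persist every stage
#'
#' Writes the simulated spectra, the split, the per-target CARS selections,
#' both comparison tables and a manifest (seed, configuration, versions)
#' sufficient to replay the run exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print one line per stage.
#' @return list with both reports and the paths written, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spectra <- simulate_study(config)
  write_spectra_csv(spectra, file.path(out_dir, "spectra.csv"))
  table1 <- run_preprocessing_comparison(config, spectra, verbose = verbose)
  res <- run_model_comparison(config, spectra, verbose = verbose)
  split <- res$split
  balance <- lapply(config$targets, function(tg) {
    y <- target_values(spectra, tg)
    balance_test(y[split$train_indices], y[split$test_indices])$p_value
  })
  names(balance) <- config$targets
  jsonlite::write_json(
    list(train_indices = split$train_indices,
         test_indices = split$test_indices,
         balance_p_values = balance),
    file.path(out_dir, "split.json"), auto_unbox = TRUE, digits = NA)
  for (tg in names(res$cars)) {
    sel <- res$cars[[tg]]
    jsonlite::write_json(
      list(target = tg,
           selected_indices = sel$selected_indices,
           selected_wavenumbers = sel$selected_wavenumbers,
           selected_fraction = sel$selected_fraction,
           best_run = sel$best_run,
           rmsecv = sel$runs$rmsecv),
      file.path(out_dir, paste0("cars_", sub("^f", "", tg), ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  write_report(table1, file.path(out_dir, "table1.csv"))
  write_report(res$report, file.path(out_dir, "table2.csv"))
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("nirstarch")),
    r_version = R.version.string,
    config = config_fingerprint(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(table1 = table1, table2 = res$report,
                 out_dir = out_dir))
}

# flat, JSON-serializable view of the configuration for the manifest
config_fingerprint <- function(config) {
  list(n_points = config$n_points,
       replicates_per_level = config$replicates_per_level,
       noise = config$endmembers$noise,
       preprocess_methods = config$preprocess_methods,
       targets = config$targets,
       train_frac = config$train_frac,
       sg = list(window = config$sg_window, polyorder = config$sg_polyorder,
                 deriv = config$sg_deriv),
       max_lvs = config$max_lvs, cv_folds = config$cv_folds,
       cars = unclass(config$cars), bka = unclass(config$bka),
       epsilon = config$epsilon)
}
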