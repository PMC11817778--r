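# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so package functions are reproducible without
#' clobbering the caller's random stream. `seed = NULL` leaves the RNG
#' untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic fold map: seeded shuffle, then contiguous blocks.
# Shared by every cross-validated routine so RMSECVs are comparable.
make_folds <- function(n, folds, seed = NULL) {
  if (folds < 2L) stop("`folds` must be at least 2", call. = FALSE)
  if (folds > n) stop("`folds` (", folds, ") exceeds the number of samples (", n, ")",
                      call. = FALSE)
  ord <- with_seed(seed, sample.int(n))
  fold_of <- integer(n)
  # cut positions into `folds` blocks of near-equal size
  sizes <- rep(n %/% folds, folds) + c(rep(1L, n %% folds), rep(0L, folds - n %% folds))
  fold_of[ord] <- rep(seq_len(folds), times = sizes)
  fold_of
}

# argmin with ties broken by the first (lowest) index
which_min_first <- function(x) which.min(x)

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
    stop("`", name, "` must be a single positive integer", call. = FALSE)
  }
  as.integer(x)
}
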