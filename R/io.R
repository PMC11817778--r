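# Wide-CSV spectra tables and machine-readable report files.
#
# One dialect only: UTF-8, comma-separated, '.' decimal; header
# `sample_id,fA,fB,fC,<wavenumber_1>,...` with wavenumbers descending and
# printed with 3 decimal places; one row per sample.

#' Write a spectra set to a wide CSV file
#'
#' @param data a [spectra_set()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_spectra_csv <- function(data, path) {
  stopifnot(inherits(data, "spectra_set"))
  header <- c("sample_id", "fA", "fB", "fC",
              sprintf("%.3f", data$wavenumbers))
  num <- cbind(data$targets$fA, data$targets$fB, data$targets$fC,
               data$absorbance)
  body <- apply(num, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = ","))
  lines <- c(paste(header, collapse = ","),
             if (nrow(num)) paste(data$sample_ids, body, sep = ","))
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e)
                    stop("cannot open '", path, "' for writing: ",
                         conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a spectra set from a wide CSV file
#'
#' Validates the dialect written by [write_spectra_csv()]: the target
#' columns must be present, the wavenumber header strictly descending, and
#' `fC` must equal `fA + fB` within 1e-6 for every row.
#'
#' @param path input file path.
#' @return a [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "fA", "fB", "fC")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("spectra file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  wn_cols <- setdiff(names(df), need)
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(wn)) {
    stop("non-numeric wavenumber column header: ",
         wn_cols[which(is.na(wn))[1]], call. = FALSE)
  }
  if (length(wn) >= 2 && any(diff(wn) >= 0)) {
    bad <- which(diff(wn) >= 0)[1]
    stop("wavenumber header must be strictly descending (violated at column ",
         wn_cols[bad + 1], ")", call. = FALSE)
  }
  absorbance <- as.matrix(df[wn_cols])
  if (anyNA(absorbance)) {
    bad <- which(is.na(absorbance), arr.ind = TRUE)[1, ]
    stop("missing absorbance value at row ", bad[1], ", column ",
         wn_cols[bad[2]], call. = FALSE)
  }
  targets <- df[c("fA", "fB", "fC")]
  bad <- which(abs(targets$fC - (targets$fA + targets$fB)) > 1e-6)
  if (length(bad)) {
    stop("fC != fA + fB at row ", bad[1], " (sample ",
         df$sample_id[bad[1]], ")", call. = FALSE)
  }
  # recompute fC so downstream invariants hold exactly
  targets$fC <- targets$fA + targets$fB
  spectra_set(absorbance, wn, targets, df$sample_id)
}

#' Write a report table to CSV and JSON twins
#'
#' Writes `<path>.csv` and `<path>.json` (or, when `path` ends in `.csv`,
#' its `.json` sibling) with identical content; numeric metrics are printed
#' with 4 decimal places, the precision the comparison tables use.
#'
#' @param report a `report_table` from [build_report()] / [eval_model()].
#' @param path output path (with or without the `.csv` extension).
#' @return character vector of the two paths written, invisibly.
#' @export
write_report <- function(report, path) {
  if (!is.data.frame(report) || nrow(report) == 0) {
    stop("report is empty", call. = FALSE)
  }
  need <- c("target", "model", "params", "RC2", "RMSEC", "RP2", "RMSEP")
  missing_cols <- setdiff(need, names(report))
  if (length(missing_cols)) {
    stop("report is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  incomplete <- !stats::complete.cases(report[c("RC2", "RMSEC", "RP2", "RMSEP")])
  if (any(incomplete)) {
    stop("report row ", which(incomplete)[1], " has missing metrics",
         call. = FALSE)
  }
  base <- sub("\\.(csv|json)$", "", path)
  out <- as.data.frame(report)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.4f", v))
  utils::write.csv(out, paste0(base, ".csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(out, paste0(base, ".json"), dataframe = "rows",
                       pretty = TRUE)
  invisible(c(paste0(base, ".csv"), paste0(base, ".json")))
}
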