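#' Construct a spectra set
#'
#' Container for a batch of NIR spectra on a shared wavenumber grid, with
#' optional per-sample reference contents for calibration.
#'
#' @param grid Wavenumbers in cm^-1, strictly ascending.
#' @param absorbance Numeric matrix, one spectrum per row, `length(grid)`
#'   columns.
#' @param sample_ids Optional identifiers, one per row.
#' @param reference Optional numeric vector of reference contents (\%), one
#'   per row.
#' @return List of class `spectra_set`.
#' @export
spectra_set <- function(grid, absorbance, sample_ids = NULL,
                        reference = NULL) {
  absorbance <- as.matrix(absorbance)
  stopifnot(is.numeric(grid), all(diff(grid) > 0),
            ncol(absorbance) == length(grid))
  if (is.null(sample_ids)) sample_ids <- seq_len(nrow(absorbance))
  stopifnot(length(sample_ids) == nrow(absorbance))
  if (!is.null(reference)) {
    stopifnot(length(reference) == nrow(absorbance))
  }
  structure(list(grid = grid, absorbance = absorbance,
                 sample_ids = sample_ids, reference = reference),
            class = "spectra_set")
}

#' Subset a spectra set by sample index
#'
#' @param spectra A `spectra_set`.
#' @param idx Integer row indices.
#' @return A `spectra_set` with the selected samples.
#' @export
spectra_subset <- function(spectra, idx) {
  spectra_set(spectra$grid,
              spectra$absorbance[idx, , drop = FALSE],
              spectra$sample_ids[idx],
              if (!is.null(spectra$reference)) spectra$reference[idx])
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra x %d points, %.0f-%.0f cm^-1%s\n",
              nrow(x$absorbance), length(x$grid), min(x$grid), max(x$grid),
              if (is.null(x$reference)) "" else ", with reference values"))
  invisible(x)
}

#' Write / read spectra as CSV
#'
#' The plain-text exchange layout used by spectrometer exports: first column
#' the wavenumber, one column per sample.
#'
#' @param spectra A `spectra_set`.
#' @param path CSV file path.
#' @return `read_spectra_csv` returns a `spectra_set` (without reference
#'   values); `write_spectra_csv` returns `path` invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- data.frame(wavenumber = spectra$grid, t(spectra$absorbance))
  names(df)[-1] <- as.character(spectra$sample_ids)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  spectra_set(df[[1]], t(as.matrix(df[-1])), sample_ids = names(df)[-1])
}

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
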