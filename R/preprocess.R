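# Spectral preprocessing for NIR absorbance spectra. All transforms operate
# per spectrum (row-wise on a samples x wavenumbers matrix), so they carry no
# state across samples and can be re-applied freely inside cross-validation
# folds.

#' Scale a spectrum to unit Euclidean norm
#'
#' @param x Numeric vector of absorbances.
#' @return Vector with `sqrt(sum(x^2)) == 1`.
#' @export
#' @examples
#' vector_normalize(c(3, 4)) # 0.6 0.8
vector_normalize <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot normalize an all-zero spectrum", call. = FALSE)
  x / nrm
}

#' Standard normal variate (SNV) transform
#'
#' Per-spectrum standardization: subtract the spectrum mean and divide by
#' its standard deviation (n-1 denominator), correcting additive baseline
#' offsets and multiplicative scatter.
#'
#' @param x Numeric vector of absorbances, non-constant.
#' @return Vector with mean 0 and standard deviation 1.
#' @export
snv <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("SNV undefined for a constant spectrum", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Savitzky-Golay first derivative of a spectrum
#'
#' Local polynomial least-squares first derivative with respect to the grid
#' coordinate (wavenumber), computed on an evenly spaced grid via
#' [signal::sgolayfilt()]. Output units are absorbance per cm^-1.
#'
#' @param x Numeric vector of absorbances.
#' @param grid Wavenumber grid (cm^-1), strictly ascending and evenly spaced;
#'   alternatively a single number giving the grid step.
#' @param window Odd filter length, greater than `polyorder`; default 15.
#' @param polyorder Polynomial order; default 2.
#' @return Vector of derivative values, same length as `x`.
#' @export
sg_first_derivative <- function(x, grid, window = 15, polyorder = 2) {
  if (window %% 2 != 1 || window <= polyorder || window > length(x)) {
    stop("window must be odd, > polyorder and <= length(x)", call. = FALSE)
  }
  if (length(grid) == 1) {
    step <- grid
  } else {
    steps <- diff(grid)
    if (any(steps <= 0) || max(steps) - min(steps) > 1e-8 * mean(steps)) {
      stop("grid must be strictly ascending and evenly spaced", call. = FALSE)
    }
    step <- mean(steps)
  }
  signal::sgolayfilt(x, p = polyorder, n = window, m = 1, ts = step)
}

#' Define a spectral preprocessing chain
#'
#' An ordered list of per-spectrum transforms applied before calibration.
#' The default order follows common NIR practice for this protocol:
#' vector normalization, then Savitzky-Golay first derivative, then SNV.
#'
#' @param steps Character vector drawn from `"normalize"`,
#'   `"sg_derivative"`, `"snv"`, applied in the order given. May be empty
#'   (`character(0)`) for no preprocessing.
#' @param window,polyorder Savitzky-Golay parameters used when
#'   `"sg_derivative"` is in the chain.
#' @return List of class `preprocess_chain`.
#' @export
preprocess_chain <- function(steps = c("normalize", "sg_derivative", "snv"),
                             window = 15, polyorder = 2) {
  allowed <- c("normalize", "sg_derivative", "snv")
  if (length(steps) > 0) stopifnot(all(steps %in% allowed))
  structure(list(steps = steps, window = window, polyorder = polyorder),
            class = "preprocess_chain")
}

#' Apply a preprocessing chain to a spectra matrix
#'
#' @param X Numeric matrix, one spectrum per row.
#' @param grid Wavenumber grid matching `ncol(X)`.
#' @param chain A [preprocess_chain()].
#' @return Matrix of the same dimensions.
#' @export
apply_chain <- function(X, grid, chain) {
  stopifnot(is.matrix(X), inherits(chain, "preprocess_chain"))
  for (step in chain$steps) {
    X <- switch(step,
      normalize = t(apply(X, 1, vector_normalize)),
      sg_derivative = t(apply(X, 1, sg_first_derivative, grid = grid,
                              window = chain$window,
                              polyorder = chain$polyorder)),
      snv = t(apply(X, 1, snv)))
  }
  X
}
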