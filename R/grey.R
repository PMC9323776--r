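# GM(1,N) multivariate grey model: one reference series driven by N-1
# comparative series. The algebraic pipeline is initialization (divide by the
# first element), one-time accumulated generating operation (cumulative sum),
# mean-generating sequence (consecutive-pair averages of the reference AGO),
# and a least-squares fit of the grey differential equation
#   X0(k) = b1*X1ago(k) + ... + bm*Xmago(k) - a*Z1(k),  k = 2..n.

#' Initialize a grey-system series
#'
#' Divides every element by the first, removing scale so that series of
#' different units (percent contents, MPa moduli) become comparable. The
#' first element of the result is exactly 1.
#'
#' @param x Numeric vector with `x[1] != 0`.
#' @return Dimensionless vector of the same length, first element 1.
#' @export
#' @examples
#' grey_initialize(c(2, 4, 6)) # 1 2 3
grey_initialize <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  if (x[1] == 0) stop("cannot initialize: first element is zero",
                      call. = FALSE)
  x / x[1]
}

#' One-time accumulated generating operation (AGO)
#'
#' Running cumulative sum of an initialized series; accumulation smooths the
#' randomness of the raw sequence before the grey fit.
#'
#' @param x Numeric vector (typically from [grey_initialize()]).
#' @return Cumulative-sum vector of the same length.
#' @export
#' @examples
#' grey_ago(c(1, 2, 3)) # 1 3 6
grey_ago <- function(x) {
  stopifnot(is.numeric(x))
  cumsum(x)
}

#' Inverse accumulated generating operation
#'
#' First-difference inverse of [grey_ago()]: the first element is preserved
#' and subsequent elements are consecutive differences, so
#' `grey_inverse_ago(grey_ago(x))` returns `x` (up to floating-point
#' round-off of the intermediate sums).
#'
#' @param x Numeric vector of accumulated values.
#' @return Vector of the same length.
#' @export
grey_inverse_ago <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  c(x[1], diff(x))
}

#' Mean-generating sequence
#'
#' Consecutive-pair averages of an accumulated series: the value at position
#' k (k = 2..n) is half the sum of the AGO values at k-1 and k. This is the
#' regression term multiplied by the development coefficient in the grey
#' differential equation.
#'
#' @param x Accumulated (AGO) numeric vector, length >= 2.
#' @return Numeric vector of length `length(x) - 1`, covering k = 2..n.
#' @export
#' @examples
#' grey_mean_sequence(c(1, 2.56)) # 1.78
grey_mean_sequence <- function(x) {
  stopifnot(is.numeric(x))
  n <- length(x)
  if (n < 2) stop("mean-generating sequence needs at least 2 values",
                  call. = FALSE)
  0.5 * (x[-n] + x[-1])
}

#' Build the grey design matrix and response
#'
#' Constructs, for k = 2..n, the regression system whose least-squares
#' solution is the coefficient vector (a, b1..bm): the response is the
#' initialized reference series at k, and the regressors are
#' (-Z1(k), X1ago(k), ..., Xmago(k)), so that the solved vector satisfies
#' the grey differential equation with the development coefficient entering
#' as "-a * Z1(k)".
#'
#' @param reference Numeric vector: the raw reference (dependent) series.
#' @param comparatives List of numeric vectors (raw comparative series), all
#'   the same length as `reference`. Optionally named.
#' @return List of class `grey_design` with elements `B` (matrix,
#'   `(n-1) x (1+m)`), `Y` (response vector, length `n-1`), `labels`.
#' @export
grey_design <- function(reference, comparatives) {
  stopifnot(is.numeric(reference), is.list(comparatives),
            length(comparatives) >= 1)
  n <- length(reference)
  lens <- vapply(comparatives, length, integer(1))
  if (any(lens != n)) {
    stop("all series must have the same length as the reference (", n, ")",
         call. = FALSE)
  }
  m <- length(comparatives)
  if (n - 1 < m + 1) {
    stop("under-determined system: ", n - 1, " equations for ", m + 1,
         " parameters", call. = FALSE)
  }
  ref0 <- grey_initialize(reference)
  ref1 <- grey_ago(ref0)
  z <- grey_mean_sequence(ref1)
  ago_mat <- vapply(comparatives,
                    function(s) grey_ago(grey_initialize(s))[-1],
                    numeric(n - 1))
  labels <- names(comparatives)
  if (is.null(labels)) labels <- paste0("X", seq_len(m))
  B <- cbind(-z, ago_mat)
  colnames(B) <- c("Z1", labels)
  structure(list(B = B, Y = ref0[-1], labels = labels),
            class = "grey_design")
}

#' Estimate grey-model coefficients by least squares
#'
#' Solves the design system for (a, b1..bm). A QR-based solver is used for
#' numerical stability; on well-conditioned inputs the result coincides with
#' the textbook normal-equations formula \eqn{(B'B)^{-1} B'Y} to machine
#' precision.
#'
#' @param design A `grey_design` object from [grey_design()].
#' @return List of class `grey_coefficients`: `a` (development coefficient)
#'   and `b` (named vector of grey action quantities).
#' @export
grey_estimate <- function(design) {
  stopifnot(inherits(design, "grey_design"))
  qrB <- qr(design$B)
  if (qrB$rank < ncol(design$B)) {
    stop("rank-deficient grey design (rank ", qrB$rank, " < ",
         ncol(design$B), " columns); condition number ",
         format(kappa(design$B), digits = 3), call. = FALSE)
  }
  theta <- qr.coef(qrB, design$Y)
  b <- theta[-1]
  names(b) <- design$labels
  structure(list(a = unname(theta[1]), b = b), class = "grey_coefficients")
}

#' @export
print.grey_coefficients <- function(x, ...) {
  cat("Grey-model coefficients\n")
  cat(sprintf("  development coefficient a: %.4f\n", x$a))
  for (i in seq_along(x$b)) {
    cat(sprintf("  grey action quantity b%d (%s): %.4f [%s]\n", i,
                names(x$b)[i], x$b[i],
                if (x$b[i] > 0) "promoter" else "inhibitor"))
  }
  invisible(x)
}

#' Predict the initialized reference value from grey coefficients
#'
#' Evaluates `sum(b_i * ago_i(k)) - a * z(k)`. Accepts a vector of AGO values
#' for one k, or a matrix with one row per k.
#'
#' @param coeffs A `grey_coefficients` object (or list with `a`, `b`).
#' @param ago_values Numeric vector of length `length(b)`, or a matrix with
#'   that many columns.
#' @param z Mean-generating value(s), one per row of `ago_values`.
#' @return Predicted initialized reference value(s).
#' @export
grey_predict <- function(coeffs, ago_values, z) {
  b <- coeffs$b
  if (is.matrix(ago_values)) {
    if (ncol(ago_values) != length(b)) {
      stop("ago_values has ", ncol(ago_values), " columns but ", length(b),
           " coefficients", call. = FALSE)
    }
    stopifnot(length(z) == nrow(ago_values))
    drop(ago_values %*% b) - coeffs$a * z
  } else {
    if (length(ago_values) != length(b)) {
      stop("ago_values has length ", length(ago_values), " but ", length(b),
           " coefficients", call. = FALSE)
    }
    stopifnot(length(z) == 1)
    sum(b * ago_values) - coeffs$a * z
  }
}

#' Grey-model error analysis
#'
#' For k = 2..n, rebuilds the regressors from the raw series (initialize,
#' accumulate, mean-generate), applies [grey_predict()] with the supplied
#' coefficients, and compares against the actual initialized reference
#' values. Relative error is |predicted - actual| / actual; the summary is
#' the arithmetic mean over k = 2..n. Each grey action quantity is
#' classified by sign: positive coefficients promote the reference series,
#' negative ones inhibit it.
#'
#' @param coeffs A `grey_coefficients` object.
#' @param reference Raw reference series.
#' @param comparatives List of raw comparative series.
#' @return List of class `grey_fit_report`: `table` (data frame with columns
#'   `k`, `predicted`, `actual`, `relative_error`), `average_relative_error`,
#'   `signs` (character vector "promoter"/"inhibitor" per coefficient),
#'   `coefficients`.
#' @export
grey_fit_report <- function(coeffs, reference, comparatives) {
  n <- length(reference)
  ref0 <- grey_initialize(reference)
  ref1 <- grey_ago(ref0)
  z <- grey_mean_sequence(ref1)
  ago_mat <- vapply(comparatives,
                    function(s) grey_ago(grey_initialize(s))[-1],
                    numeric(n - 1))
  grey_report_from_values(coeffs, ago_mat, z, actual = ref0[-1],
                          k = seq(2, n))
}

# Shared error-analysis core: regressors and actuals supplied directly, so
# the same code serves both the recomputed pipeline and reproduction from
# printed sequence tables.
grey_report_from_values <- function(coeffs, ago_mat, z, actual, k) {
  if (any(actual == 0)) {
    stop("actual initialized value is zero at some k; relative error undefined",
         call. = FALSE)
  }
  pred <- grey_predict(coeffs, ago_mat, z)
  rel <- abs(pred - actual) / abs(actual)
  tab <- data.frame(k = k, predicted = pred, actual = actual,
                    relative_error = rel)
  signs <- ifelse(coeffs$b > 0, "promoter", "inhibitor")
  names(signs) <- names(coeffs$b)
  structure(list(table = tab,
                 average_relative_error = mean(rel),
                 signs = signs,
                 coefficients = coeffs),
            class = "grey_fit_report")
}

#' @export
print.grey_fit_report <- function(x, ...) {
  cat("Grey-model error analysis (k = ", min(x$table$k), "..",
      max(x$table$k), ")\n", sep = "")
  print(transform(x$table,
                  predicted = round(predicted, 2),
                  actual = round(actual, 2),
                  relative_error = round(relative_error, 2)),
        row.names = FALSE)
  cat(sprintf("average relative error: %.2f\n", x$average_relative_error))
  for (nm in names(x$signs)) {
    cat(sprintf("  %s: %s\n", nm, x$signs[nm]))
  }
  invisible(x)
}

#' Fit a GM(1,N) model end to end
#'
#' Convenience wrapper: builds the design from the raw series, estimates the
#' coefficients and returns them with the corresponding error analysis.
#'
#' @inheritParams grey_design
#' @return List with `coefficients` (`grey_coefficients`) and `report`
#'   (`grey_fit_report`).
#' @export
grey_fit <- function(reference, comparatives) {
  design <- grey_design(reference, comparatives)
  coeffs <- grey_estimate(design)
  list(coefficients = coeffs,
       report = grey_fit_report(coeffs, reference, comparatives))
}

#' Published GM(1,4) coefficients
#'
#' The development coefficient and grey action quantities of the published
#' palm-fiber GM(1,4) model: a = 0.3129, b = (0.5292, -0.9558, 1.1413).
#' Used by the reproduction pipeline to re-evaluate the published error
#' analysis.
#'
#' @return A `grey_coefficients` object.
#' @export
published_grey_coefficients <- function() {
  structure(list(a = 0.3129,
                 b = c(X1 = 0.5292, X2 = -0.9558, X3 = 1.1413)),
            class = "grey_coefficients")
}

#' Reproduce the published grey-model computation
#'
#' Runs the GM(1,4) pipeline on the packaged data in one of two modes:
#' \describe{
#'   \item{`"printed"`}{takes the published cumulative/mean sequences
#'     verbatim ([load_grey_table()]) as regressors, actuals as the printed
#'     moduli divided by the first modulus, and evaluates the published
#'     coefficients ([published_grey_coefficients()]). This reproduces the
#'     published error table.}
#'   \item{`"recomputed"`}{rebuilds all sequences from the composition table
#'     (samples 1-15) and the printed moduli via
#'     initialize/accumulate/mean-generate, re-estimates the coefficients by
#'     least squares, and reports with those. `comparative_order` selects
#'     which composition columns play comparative series 1..3: `"stated"`
#'     follows the stated ordering (cellulose, hemicellulose, lignin);
#'     `"table_evidence"` follows the ordering suggested by the numeric
#'     agreement of the printed cumulative columns (lignin, hemicellulose,
#'     cellulose). The source is ambiguous, so both are available.}
#' }
#' In both modes the coefficients re-estimated from the mode's own design
#' are attached as a diagnostic, together with their deviation from the
#' published values; agreement is reported, not asserted, because the
#' published inputs are rounded to 2 decimals and one column identity is
#' ambiguous.
#'
#' @param mode `"printed"` or `"recomputed"`.
#' @param comparative_order For `"recomputed"`: `"stated"` or
#'   `"table_evidence"`.
#' @return List of class `grey_reproduction`: `mode`, `report`
#'   (`grey_fit_report`), `coefficients_used`, `coefficients_reestimated`,
#'   `coefficient_deviation` (max absolute difference from the published
#'   values), `sequences` (data frame of the regressor sequences used).
#' @export
grey_reproduction <- function(mode = c("printed", "recomputed"),
                              comparative_order = c("stated",
                                                    "table_evidence")) {
  mode <- match.arg(mode)
  comparative_order <- match.arg(comparative_order)
  fits <- load_tensile_fits()
  moduli <- fits$e_printed

  if (mode == "printed") {
    grey <- load_grey_table()
    ago_mat <- as.matrix(grey[-1, c("x1_cum", "x2_cum", "x3_cum")])
    z <- grey$z1[-1]
    actual <- grey_initialize(moduli)[-1]
    coeffs <- published_grey_coefficients()
    report <- grey_report_from_values(coeffs, ago_mat, z, actual,
                                      k = grey$k[-1])
    # diagnostic re-estimation on the printed design
    design <- structure(list(B = cbind(-z, ago_mat), Y = actual,
                             labels = colnames(ago_mat)),
                        class = "grey_design")
    reest <- grey_estimate(design)
    sequences <- grey
  } else {
    comps <- load_components()[1:15, ]
    order_cols <- switch(comparative_order,
                         stated = c("cellulose", "hemicellulose", "lignin"),
                         table_evidence = c("lignin", "hemicellulose",
                                            "cellulose"))
    comparatives <- lapply(comps[order_cols], identity)
    design <- grey_design(moduli, comparatives)
    reest <- grey_estimate(design)
    coeffs <- reest
    report <- grey_fit_report(coeffs, moduli, comparatives)
    ref1 <- grey_ago(grey_initialize(moduli))
    sequences <- data.frame(
      k = 1:15,
      vapply(comparatives, function(s) grey_ago(grey_initialize(s)),
             numeric(15)),
      x0_cum = ref1,
      z1 = c(NA, grey_mean_sequence(ref1)))
  }

  published <- published_grey_coefficients()
  dev <- max(abs(c(reest$a - published$a, reest$b - published$b)))
  structure(list(mode = mode,
                 comparative_order = if (mode == "recomputed")
                   comparative_order else NA_character_,
                 report = report,
                 coefficients_used = coeffs,
                 coefficients_reestimated = reest,
                 coefficient_deviation = dev,
                 sequences = sequences),
            class = "grey_reproduction")
}

#' @export
print.grey_reproduction <- function(x, ...) {
  cat("Grey-model reproduction, mode:", x$mode, "\n")
  print(x$report)
  cat(sprintf("re-estimated (a, b): %.4f, %s\n",
              x$coefficients_reestimated$a,
              paste(sprintf("%.4f", x$coefficients_reestimated$b),
                    collapse = ", ")))
  cat(sprintf("max |deviation| from published coefficients: %.4f\n",
              x$coefficient_deviation))
  invisible(x)
}
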