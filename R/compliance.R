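#' Young's modulus from the slope of the compliance line
#'
#' In the system-compliance method the measured displacement per unit force
#' of a single-fiber tensile test is regressed on gauge length over
#' cross-sectional area; the slope of that line has units mm^2/N = 1/MPa, so
#' Young's modulus is its reciprocal and the intercept is the compliance of
#' the load train.
#'
#' @param slope Slope of the `dl_over_f` vs `l0_over_a` line, mm^2/N. Must be
#'   positive.
#' @return Young's modulus in MPa.
#' @export
#' @examples
#' modulus_from_slope(0.00114)    # 877.19 MPa
#' modulus_from_slope(3.87646e-4) # 2579.67 MPa
modulus_from_slope <- function(slope) {
  if (!is.numeric(slope) || any(!is.finite(slope)) || any(slope <= 0)) {
    stop("slope must be positive and finite; Young's modulus is 1/slope",
         call. = FALSE)
  }
  1 / slope
}

#' Fit the system-compliance line to single-fiber tensile points
#'
#' Ordinary least squares of displacement-per-force (mm/N) on gauge length
#' over cross-sectional area (1/mm), with intercept. The reciprocal of the
#' fitted slope is Young's modulus (MPa); the intercept is the system
#' compliance Cs (mm/N). Negative intercepts are physically admissible (they
#' occur in published fits); a non-positive slope is not, and is rejected.
#'
#' @param points A data frame with numeric columns `l0_over_a` (1/mm, > 0)
#'   and `dl_over_f` (mm/N). At least two points with at least two distinct
#'   `l0_over_a` values are required.
#' @return An object of class `compliance_fit`: a list with elements `slope`
#'   (mm^2/N), `cs` (mm/N), `e` (MPa, exactly `1/slope`), `r2`, `n_points`.
#' @export
#' @examples
#' pts <- data.frame(l0_over_a = c(100, 200, 300),
#'                   dl_over_f = 0.001 * c(100, 200, 300) + 0.1)
#' fit_compliance_line(pts)
fit_compliance_line <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("l0_over_a", "dl_over_f") %in% names(points)))
  x <- points$l0_over_a
  y <- points$dl_over_f
  if (length(x) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(x <= 0)) stop("l0_over_a must be positive", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("degenerate design: all l0_over_a values identical; ",
         "test at least two gauge-length/area ratios", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  cs <- unname(stats::coef(fit)[1])
  if (slope <= 0) {
    stop(sprintf("non-physical fitted slope %.6g <= 0 (modulus undefined)",
                 slope), call. = FALSE)
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = slope, cs = cs, e = 1 / slope, r2 = r2,
                 n_points = length(x)),
            class = "compliance_fit")
}

#' @export
print.compliance_fit <- function(x, ...) {
  cat(sprintf(
    "Compliance-line fit (%d points)\n  slope: %.6g mm^2/N\n  Cs:    %.5f mm/N\n  E:     %.2f MPa\n  R^2:   %.3f\n",
    x$n_points, x$slope, x$cs, x$e, x$r2))
  invisible(x)
}

#' Reduce raw tensile records to compliance points
#'
#' Converts raw single-fiber test records to the coordinates of the
#' compliance line by exact division: `l0_over_a = gauge_length_mm /
#' area_mm2` and `dl_over_f = displacement_mm / force_N`. By default every
#' test is kept as its own point; optionally replicates at the same
#' gauge-length/area ratio are averaged.
#'
#' @param records Data frame with columns `gauge_length_mm`, `area_mm2`,
#'   `displacement_mm`, `force_N`.
#' @param aggregate If `TRUE`, average `dl_over_f` across records sharing an
#'   identical `l0_over_a`. Default `FALSE`.
#' @return Data frame with columns `l0_over_a`, `dl_over_f`.
#' @export
reduce_tensile_records <- function(records, aggregate = FALSE) {
  needed <- c("gauge_length_mm", "area_mm2", "displacement_mm", "force_N")
  stopifnot(is.data.frame(records), all(needed %in% names(records)))
  pts <- data.frame(l0_over_a = records$gauge_length_mm / records$area_mm2,
                    dl_over_f = records$displacement_mm / records$force_N)
  if (aggregate) {
    agg <- stats::aggregate(dl_over_f ~ l0_over_a, data = pts, FUN = mean)
    pts <- agg[order(agg$l0_over_a), ]
    rownames(pts) <- NULL
  }
  pts
}

#' Read compliance points from CSV
#'
#' Accepts either pre-reduced points (`l0_over_a`, `dl_over_f`) or raw test
#' records (`gauge_length_mm`, `area_mm2`, `displacement_mm`, `force_N`),
#' which are reduced via [reduce_tensile_records()].
#'
#' @param path CSV file path.
#' @param aggregate Passed to [reduce_tensile_records()] for raw records.
#' @return Data frame with columns `l0_over_a`, `dl_over_f`.
#' @export
read_compliance_points <- function(path, aggregate = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("l0_over_a", "dl_over_f") %in% names(df))) {
    df[, c("l0_over_a", "dl_over_f")]
  } else {
    reduce_tensile_records(df, aggregate = aggregate)
  }
}

#' Recompute the published moduli from the published slopes
#'
#' For each tensile-tested sample, takes the slope parsed from the printed
#' line equation, recomputes E = 1/slope, and compares it with the printed
#' modulus. Rows whose relative deviation exceeds `tol` are flagged; these
#' deviations feed the errata report.
#'
#' @param fits Data frame from [load_tensile_fits()] (the default).
#' @param tol Relative-deviation threshold for flagging; default 0.01 (1\%).
#' @return Data frame with columns `sample_id`, `e_recomputed`, `e_printed`,
#'   `relative_deviation`, `flagged`.
#' @export
reproduce_table6 <- function(fits = load_tensile_fits(), tol = 0.01) {
  e_re <- modulus_from_slope(fits$slope)
  dev <- abs(e_re - fits$e_printed) / fits$e_printed
  data.frame(sample_id = fits$sample_id,
             e_recomputed = e_re,
             e_printed = fits$e_printed,
             relative_deviation = dev,
             flagged = dev > tol)
}
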