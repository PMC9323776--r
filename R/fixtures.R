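#' @importFrom utils read.csv write.csv
NULL

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "fiberGM")
  if (identical(path, "") || !file.exists(path)) {
    stop("fixture file not found: ", name, call. = FALSE)
  }
  path
}

read_fixture <- function(name) {
  df <- tryCatch(
    read.csv(fixture_path(name), stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("failed to read fixture '", name, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  df
}

#' Chemical composition of the 26 palm samples
#'
#' Loads the packaged table of cellulose, hemicellulose and lignin contents
#' (percent by mass) for the 26 windmill-palm samples: 20 fibers at different
#' degrees of degumming plus petiole, leaf-sheath and fruit-bunch material and
#' the fibers extracted from them. Values are stored verbatim at the printed
#' precision (2 decimal places); no corrections are applied.
#'
#' @return A data frame with columns `sample_id`, `cellulose`,
#'   `hemicellulose`, `lignin` (26 rows, in sample order).
#' @seealso [consistency_report()] for known internal inconsistencies of the
#'   printed tables.
#' @export
#' @examples
#' comps <- load_components()
#' comps[comps$sample_id == 8, ]
load_components <- function() {
  df <- read_fixture("components.csv")
  stopifnot(nrow(df) == 26, !anyDuplicated(df$sample_id))
  df
}

# Parses the slope coefficient out of a printed line-equation string such as
# "DL/F = 7.2952 × 10^−4 L0/A + 0.14939" or plain "0.00114"; accepts unicode
# multiplication sign/minus as well as ASCII "e-4" scientific notation.
parse_slope <- function(equation) {
  rhs <- sub(".*=", "", equation)
  rhs <- trimws(rhs)
  # normalize unicode minus and multiplication sign
  rhs <- gsub("−", "-", rhs)
  rhs <- gsub("×", "x", rhs)
  # coefficient is everything up to "L0/A"
  coef_str <- trimws(sub("L0/A.*", "", rhs))
  # "a x 10^-4" -> "ae-4"
  coef_str <- gsub("\\s*x\\s*10\\^", "e", coef_str)
  value <- suppressWarnings(as.numeric(coef_str))
  if (is.na(value)) {
    stop("cannot parse slope from line equation: '", equation, "'",
         call. = FALSE)
  }
  value
}

#' Compliance-line fits of the 15 tensile-tested samples
#'
#' Loads the printed per-sample results of the system-compliance analysis:
#' the fitted line equation of displacement-per-force against gauge length
#' over area, its intercept (system compliance Cs, mm/N), the printed Young's
#' modulus E (MPa) and R-squared. The slope (mm^2/N) is parsed from the
#' line-equation string, which mixes decimal and scientific notation.
#'
#' Five printed rows have E inconsistent with 1/slope; see
#' [consistency_report()]. Values are returned verbatim.
#'
#' @return A data frame with columns `sample_id`, `line_equation`, `slope`,
#'   `cs`, `e_printed`, `r2` (15 rows).
#' @export
load_tensile_fits <- function() {
  df <- read_fixture("tensile_fits.csv")
  stopifnot(nrow(df) == 15)
  df$slope <- vapply(df$line_equation, parse_slope, numeric(1),
                     USE.NAMES = FALSE)
  df[, c("sample_id", "line_equation", "slope", "cs", "e_printed", "r2")]
}

#' External-validation pairs for the NIR calibration
#'
#' Measured versus NIR-predicted contents for the three external-validation
#' samples (8, 23 and 26), for each of the three components, together with
#' the printed absolute errors.
#'
#' @return A data frame with columns `sample_id`, `component`, `measured`,
#'   `predicted`, `abs_error_printed` (9 rows).
#' @export
load_validation <- function() {
  df <- read_fixture("validation.csv")
  stopifnot(nrow(df) == 9)
  df
}

#' Printed cumulative and mean-generating sequences of the grey model
#'
#' Loads the published table of one-time accumulated generating (AGO)
#' sequences for the three comparative series and the reference
#' (Young's-modulus) series, plus the mean-generating sequence Z1, for
#' samples 1-15. Column names follow the printed order `x1_cum` .. `x3_cum`;
#' the mapping of those columns onto cellulose/hemicellulose/lignin is
#' ambiguous in the source (see [consistency_report()]), so no component
#' labels are attached here.
#'
#' @return A data frame with columns `k`, `x1_cum`, `x2_cum`, `x3_cum`,
#'   `x0_cum`, `z1` (`z1` is `NA` at k = 1).
#' @export
load_grey_table <- function() {
  df <- read_fixture("grey_table.csv")
  stopifnot(nrow(df) == 15, identical(df$k, 1:15))
  df
}

#' Printed grey-model error analysis
#'
#' Loads the published per-row predicted and actual (initialized) modulus
#' values and relative errors. The printed average relative error is attached
#' as attribute `average_relative_error`. The final printed row duplicates
#' the first; it is kept verbatim and flagged by [consistency_report()].
#'
#' @return A data frame with columns `row`, `predicted`, `actual`,
#'   `relative_error` (15 rows) and attribute `average_relative_error`.
#' @export
load_error_table <- function() {
  df <- read_fixture("error_table.csv")
  avg <- df$relative_error[df$row == "average"]
  out <- df[df$row != "average", ]
  out$row <- as.integer(out$row)
  stopifnot(nrow(out) == 15, length(avg) == 1)
  attr(out, "average_relative_error") <- avg
  out
}

#' Literature composition ranges for windmill-palm material
#'
#' Reference-only table of cellulose/hemicellulose/lignin contents reported
#' for leaf sheaths, trunks, fruit bunches and mesocarp, carried for
#' documentation; not used by any computation.
#'
#' @return A data frame with columns `component`, `source`, `value_low`,
#'   `value_high`, `kind`.
#' @export
load_literature_ranges <- function() {
  read_fixture("literature_ranges.csv")
}

errata_flag <- function(table, location, kind, detail) {
  data.frame(table = table, location = location, kind = kind,
             detail = detail, stringsAsFactors = FALSE)
}

#' Internal-consistency report over the packaged tables
#'
#' Cross-checks the printed tables against one another and against the
#' arithmetic that links them, and returns one flag per discrepancy found.
#' Checks performed:
#' \itemize{
#'   \item reciprocal check: rows of the compliance table where the printed
#'     modulus differs from the reciprocal of the printed slope by more than
#'     1\% relative (`reciprocal_mismatch`);
#'   \item identity of the cumulative columns of the grey-sequence table:
#'     each is compared against the accumulated, initialized version of every
#'     composition column over samples 1-15; a column matching none of them
#'     within rounding (+-0.011 everywhere) is flagged
#'     (`column_identity_ambiguous`);
#'   \item the reference cumulative value at k = 12 versus the value implied
#'     by the printed moduli (`internal_sum_mismatch`);
#'   \item the duplicated final row of the error-analysis table
#'     (`duplicated_row`);
#'   \item calibration-set composition ranges stated in the text versus the
#'     extremes of the composition table (`text_table_conflict`);
#'   \item validation-table absolute errors that do not equal
#'     |measured - predicted| at printed precision (`internal_sum_mismatch`).
#' }
#'
#' Flags describe the printed data; nothing is corrected silently.
#'
#' @return A data frame of flags with columns `table`, `location`, `kind`,
#'   `detail`.
#' @export
consistency_report <- function() {
  flags <- list()

  # (a) reciprocal check on the compliance table
  fits <- load_tensile_fits()
  recomputed <- 1 / fits$slope
  rel <- abs(recomputed - fits$e_printed) / fits$e_printed
  for (i in which(rel > 0.01)) {
    flags[[length(flags) + 1L]] <- errata_flag(
      "tensile_fits", sprintf("row %d", fits$sample_id[i]),
      "reciprocal_mismatch",
      sprintf("1/slope = %.2f MPa but printed E = %.2f MPa (%.1f%% apart)",
              recomputed[i], fits$e_printed[i], 100 * rel[i]))
  }

  # (b) identity of the grey-table cumulative columns
  comps <- load_components()[1:15, ]
  grey <- load_grey_table()
  ago_of <- function(x) cumsum(x / x[1])
  candidates <- list(cellulose = ago_of(comps$cellulose),
                     hemicellulose = ago_of(comps$hemicellulose),
                     lignin = ago_of(comps$lignin))
  for (col in c("x1_cum", "x2_cum", "x3_cum")) {
    matches <- vapply(candidates, function(cand) {
      all(abs(cand - grey[[col]]) <= 0.011)
    }, logical(1))
    if (!any(matches)) {
      # report the best partial match to make the ambiguity concrete
      depth <- vapply(candidates, function(cand) {
        ok <- abs(cand - grey[[col]]) <= 0.011
        if (!ok[1]) 0L else max(which(cumsum(!ok) == 0))
      }, integer(1))
      best <- names(which.max(depth))
      k_div <- max(depth) + 1L
      flags[[length(flags) + 1L]] <- errata_flag(
        "grey_table", col, "column_identity_ambiguous",
        sprintf(paste0("matches no composition sequence at all k; closest is ",
                       "%s (agrees through k = %d; at k = %d printed %.2f ",
                       "vs %.2f implied)"),
                best, max(depth), k_div, grey[[col]][k_div],
                candidates[[best]][k_div]))
    }
  }

  # (c) reference cumulative value at k = 12 vs the printed moduli
  implied <- cumsum(fits$e_printed / fits$e_printed[1])
  if (abs(implied[12] - grey$x0_cum[12]) > 0.011) {
    flags[[length(flags) + 1L]] <- errata_flag(
      "grey_table", "x0_cum row 12", "internal_sum_mismatch",
      sprintf("printed cumulative %.2f but the printed moduli imply %.2f",
              grey$x0_cum[12], implied[12]))
  }

  # (d) duplicated final row of the error table
  err <- load_error_table()
  first <- err[1, c("predicted", "actual", "relative_error")]
  last <- err[nrow(err), c("predicted", "actual", "relative_error")]
  if (isTRUE(all.equal(unlist(first), unlist(last),
                       check.attributes = FALSE))) {
    flags[[length(flags) + 1L]] <- errata_flag(
      "error_table", sprintf("row %d", err$row[nrow(err)]), "duplicated_row",
      sprintf("row labelled %d repeats row %d's values %.2f/%.2f/%.2f",
              err$row[nrow(err)], err$row[1], first$predicted, first$actual,
              first$relative_error))
  }

  # (e) calibration-set ranges stated in the text vs the composition table
  all_comps <- load_components()
  calib <- all_comps[!all_comps$sample_id %in% c(8, 23, 26), ]
  stated <- list(cellulose = c(38.02, 76.97),
                 hemicellulose = c(10.33, 20.96),
                 lignin = c(7.93, 28.24))
  for (comp in names(stated)) {
    actual <- range(calib[[comp]])
    if (any(abs(actual - stated[[comp]]) > 0.005)) {
      flags[[length(flags) + 1L]] <- errata_flag(
        "components", comp, "text_table_conflict",
        sprintf(paste0("text states calibration %s spans %.2f-%.2f%% but the ",
                       "table's calibration extremes are %.2f-%.2f%%"),
                comp, stated[[comp]][1], stated[[comp]][2],
                actual[1], actual[2]))
    }
  }

  # (f) validation-table absolute errors vs |measured - predicted|
  val <- load_validation()
  recomputed_err <- round(abs(val$measured - val$predicted), 2)
  for (i in which(abs(recomputed_err - val$abs_error_printed) > 0.005)) {
    flags[[length(flags) + 1L]] <- errata_flag(
      "validation", sprintf("sample %d %s", val$sample_id[i],
                            val$component[i]),
      "internal_sum_mismatch",
      sprintf("printed absolute error %.2f but |%.2f - %.2f| = %.2f",
              val$abs_error_printed[i], val$measured[i], val$predicted[i],
              recomputed_err[i]))
  }

  do.call(rbind, flags)
}

#' Write the errata report as JSON
#'
#' @param report A data frame from [consistency_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_errata_json <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}
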