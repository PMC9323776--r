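# Single-response PLS regression (PLS1, NIPALS deflation) with the
# cross-validation statistics used in NIR calibration: RMSEC / Rc^2 on the
# training fit and RMSEP / Rcv^2 from held-out predictions. Predictors and
# response are mean-centered, not scaled. For a single response the NIPALS
# weight vector has the closed form w = X'y / ||X'y||, so the fit is fully
# deterministic.

pls1_core <- function(X, y, n_factors) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n_factors < 1 || n_factors > min(n - 1, p)) {
    stop("n_factors must be in 1..min(n-1, p) = ", min(n - 1, p),
         call. = FALSE)
  }
  xmean <- colMeans(X)
  ymean <- mean(y)
  Xc <- sweep(X, 2, xmean)
  yc <- y - ymean
  W <- matrix(0, p, n_factors)
  P <- matrix(0, p, n_factors)
  q <- numeric(n_factors)
  for (h in seq_len(n_factors)) {
    w <- drop(crossprod(Xc, yc))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-300) {          # residual response orthogonal to predictors
      W <- W[, seq_len(h - 1), drop = FALSE]
      P <- P[, seq_len(h - 1), drop = FALSE]
      q <- q[seq_len(h - 1)]
      break
    }
    w <- w / wn
    t_score <- drop(Xc %*% w)
    tt <- sum(t_score^2)
    p_load <- drop(crossprod(Xc, t_score)) / tt
    q_load <- sum(yc * t_score) / tt
    Xc <- Xc - tcrossprod(t_score, p_load)
    yc <- yc - t_score * q_load
    W[, h] <- w; P[, h] <- p_load; q[h] <- q_load
  }
  if (ncol(W) == 0) {
    beta <- numeric(p)
  } else {
    beta <- drop(W %*% solve(crossprod(P, W), q))
  }
  list(xmean = xmean, ymean = ymean, W = W, P = P, q = q,
       coefficients = beta, intercept = ymean - sum(xmean * beta),
       n_factors = ncol(W))
}

#' Fit a PLS calibration model for one component
#'
#' Preprocesses the spectra with the given chain, mean-centers, and fits a
#' single-response partial-least-squares model with `n_factors` latent
#' variables. Deterministic for fixed input.
#'
#' @param spectra A `spectra_set` (see [spectra_set()]) whose `reference`
#'   holds the component contents (\%) to calibrate against.
#' @param chain A [preprocess_chain()]; default the standard chain.
#' @param n_factors Number of latent variables (the calibration's "PCs").
#' @return Object of class `pls_model`: regression vector and intercept on
#'   the preprocessed scale, centering vectors, latent structure (`W`, `P`,
#'   `q`), the chain and grid used, and training predictions.
#' @export
fit_pls <- function(spectra, chain = preprocess_chain(), n_factors) {
  stopifnot(inherits(spectra, "spectra_set"), !is.null(spectra$reference))
  Xp <- apply_chain(spectra$absorbance, spectra$grid, chain)
  core <- pls1_core(Xp, spectra$reference, n_factors)
  fitted <- drop(Xp %*% core$coefficients) + core$intercept
  structure(c(core, list(chain = chain, grid = spectra$grid,
                         fitted = fitted)),
            class = "pls_model")
}

#' Predict component contents from spectra
#'
#' @param object A `pls_model`.
#' @param spectra A `spectra_set` on the same wavenumber grid.
#' @param ... Unused.
#' @return Numeric vector of predicted contents (\%).
#' @export
predict.pls_model <- function(object, spectra, ...) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (length(spectra$grid) != length(object$grid) ||
      any(spectra$grid != object$grid)) {
    stop("prediction spectra are not on the model's wavenumber grid",
         call. = FALSE)
  }
  Xp <- apply_chain(spectra$absorbance, spectra$grid, object$chain)
  drop(Xp %*% object$coefficients) + object$intercept
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
r2_about_mean <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Calibration and cross-validation statistics
#'
#' Fits the model on all samples (RMSEC, Rc^2 from the training residuals)
#' and computes held-out predictions by leave-one-out (default) or seeded
#' k-fold cross-validation, refitting preprocessing and PLS inside each fold
#' (RMSEP, Rcv^2 from the held-out residuals). Rcv^2 is 1 - PRESS/TSS about
#' the full-sample mean and may be negative for uninformative predictors; it
#' is reported unclamped.
#'
#' @inheritParams fit_pls
#' @param scheme `"loo"` (default) or an integer number of folds.
#' @param seed Seed for the fold assignment when `scheme` is a fold count.
#' @return List of class `calibration_stats`: `rmsec`, `r2c`, `rmsep`,
#'   `r2cv`, `n_factors`, `cv_predictions`.
#' @export
cross_validate <- function(spectra, chain = preprocess_chain(), n_factors,
                           scheme = "loo", seed = 1) {
  stopifnot(inherits(spectra, "spectra_set"))
  y <- spectra$reference
  n <- length(y)
  full <- fit_pls(spectra, chain, n_factors)
  if (identical(scheme, "loo")) {
    folds <- as.list(seq_len(n))
  } else {
    k <- as.integer(scheme)
    if (is.na(k) || k < 2 || k > n) {
      stop("scheme must be \"loo\" or a fold count in 2..n", call. = FALSE)
    }
    assignment <- with_seed(seed, sample(rep_len(seq_len(k), n)))
    folds <- split(seq_len(n), assignment)
    if (any(lengths(folds) >= n - 1)) {
      stop("cross-validation fold leaves fewer than 2 training samples",
           call. = FALSE)
    }
  }
  cv_pred <- numeric(n)
  for (fold in folds) {
    train <- spectra_subset(spectra, setdiff(seq_len(n), fold))
    test <- spectra_subset(spectra, fold)
    model <- fit_pls(train, chain, n_factors)
    cv_pred[fold] <- predict(model, test)
  }
  structure(list(rmsec = rmse(y, full$fitted),
                 r2c = r2_about_mean(y, full$fitted),
                 rmsep = rmse(y, cv_pred),
                 r2cv = r2_about_mean(y, cv_pred),
                 n_factors = full$n_factors,
                 cv_predictions = cv_pred),
            class = "calibration_stats")
}

#' Choose the number of PLS factors by cross-validated error
#'
#' Evaluates 1..`max_factors` latent variables and returns the count with
#' the smallest RMSEP; ties break toward fewer factors.
#'
#' @inheritParams cross_validate
#' @param max_factors Largest factor count to try.
#' @return Integer factor count.
#' @export
select_factors <- function(spectra, chain = preprocess_chain(), max_factors,
                           scheme = "loo", seed = 1) {
  stopifnot(max_factors >= 1)
  rmseps <- vapply(seq_len(max_factors), function(a) {
    cross_validate(spectra, chain, a, scheme = scheme, seed = seed)$rmsep
  }, numeric(1))
  which.min(rmseps)   # which.min returns the first (smallest) index on ties
}

#' Paired two-tailed t-test of measured versus predicted values
#'
#' The external-validation endpoint: per-sample absolute errors and the
#' paired two-tailed t statistic on the differences d = predicted - measured
#' (sample standard deviation, n-1 denominator), compared against the
#' two-sided critical value at alpha = 0.05 with df = n-1 (4.303 for n = 3).
#' If the differences have zero spread but nonzero mean, |t| is infinite and
#' the difference is reported as significant.
#'
#' @param measured,predicted Numeric vectors of equal length >= 2.
#' @return List of class `external_validation`: `measured`, `predicted`,
#'   `abs_error`, `t_abs`, `df`, `t_critical`, `significant`.
#' @export
validation_ttest <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted))
  n <- length(measured)
  if (n < 2) stop("need at least 2 validation samples", call. = FALSE)
  d <- predicted - measured
  if (stats::sd(d) == 0) {
    t_abs <- if (mean(d) == 0) 0 else Inf
  } else {
    t_abs <- abs(unname(stats::t.test(predicted, measured,
                                      paired = TRUE)$statistic))
  }
  df <- n - 1
  t_crit <- stats::qt(0.975, df)
  structure(list(measured = measured, predicted = predicted,
                 abs_error = abs(measured - predicted),
                 t_abs = t_abs, df = df, t_critical = t_crit,
                 significant = t_abs > t_crit),
            class = "external_validation")
}

#' External validation of a PLS model on held-out spectra
#'
#' Predicts the held-out samples and runs [validation_ttest()] against their
#' reference values.
#'
#' @param model A `pls_model`.
#' @param spectra A `spectra_set` with `reference` values, >= 2 samples.
#' @return An `external_validation` object.
#' @export
external_validate <- function(model, spectra) {
  stopifnot(inherits(spectra, "spectra_set"), !is.null(spectra$reference))
  pred <- predict(model, spectra)
  validation_ttest(spectra$reference, pred)
}

#' @export
print.external_validation <- function(x, ...) {
  cat("External validation\n")
  print(data.frame(measured = x$measured, predicted = round(x$predicted, 2),
                   abs_error = round(x$abs_error, 2)), row.names = FALSE)
  cat(sprintf("|t| = %.3f vs t_crit(df=%d) = %.3f: %ssignificant\n",
              x$t_abs, x$df, x$t_critical,
              if (x$significant) "" else "not "))
  invisible(x)
}
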