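# Independent closed-form oracles used to cross-check the implementation.

# OLS slope/intercept by the explicit normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# paired two-tailed t statistic by hand
ttest_oracle <- function(measured, predicted) {
  d <- predicted - measured
  abs(mean(d) / (sd(d) / sqrt(length(d))))
}

# least squares by the explicit normal-equations formula
normal_eq_oracle <- function(B, Y) {
  unname(drop(solve(t(B) %*% B) %*% t(B) %*% Y))
}

# noise-free spectra on a small grid, for fast chemometrics tests
clean_spectra <- function(components, grid = seq(4000, 9000, by = 25)) {
  simulate_spectra(components, grid = grid,
                   baseline_offset = c(0, 0), baseline_slope = c(0, 0),
                   scatter = c(1, 1), noise_sd = 0, seed = 1)
}

with_reference <- function(spectra, values) {
  spectra$reference <- values
  spectra
}
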