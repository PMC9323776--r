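test_that("vector normalization scales to unit norm and is idempotent", {
  expect_equal(vector_normalize(c(3, 4)), c(0.6, 0.8))
  set.seed(2)
  x <- stats::rnorm(200)
  nx <- vector_normalize(x)
  expect_equal(sqrt(sum(nx^2)), 1, tolerance = 1e-12)
  expect_equal(vector_normalize(nx), nx)
  expect_error(vector_normalize(rep(0, 5)), "all-zero")
})

test_that("SNV standardizes each spectrum and is affine invariant", {
  set.seed(3)
  x <- stats::rnorm(150, mean = 5, sd = 2)
  sx <- snv(x)
  expect_equal(mean(sx), 0, tolerance = 1e-12)
  expect_equal(stats::sd(sx), 1, tolerance = 1e-12)
  expect_equal(sx, (x - mean(x)) / stats::sd(x))
  expect_equal(snv(3 + 2.5 * x), snv(x))
  expect_error(snv(rep(1, 10)), "constant")
})

test_that("Savitzky-Golay derivative matches analytic derivatives", {
  grid <- seq(4000, 5000, by = 5)
  a <- 3e-4; b <- 0.2
  d_lin <- sg_first_derivative(a * grid + b, grid)
  interior <- 10:190
  expect_equal(d_lin[interior], rep(a, length(interior)), tolerance = 1e-8)
  expect_equal(sg_first_derivative(rep(2, length(grid)), grid),
               rep(0, length(grid)), tolerance = 1e-12)
  quad <- 1e-7 * (grid - 4500)^2
  d_quad <- sg_first_derivative(quad, grid, window = 11, polyorder = 2)
  expect_equal(d_quad[interior], 2e-7 * (grid[interior] - 4500),
               tolerance = 1e-6)
  expect_error(sg_first_derivative(quad, grid, window = 10), "odd")
})

test_that("PLS fits noise-free three-component mixtures exactly", {
  comps <- simulate_components(20, structure = "independent", seed = 4)
  sp <- with_reference(clean_spectra(comps), comps$cellulose)
  model <- fit_pls(sp, preprocess_chain(character(0)), n_factors = 3)
  expect_lt(sqrt(mean((model$fitted - sp$reference)^2)), 1e-6)
})

test_that("constant response yields constant predictions", {
  comps <- simulate_components(10, structure = "independent", seed = 5)
  sp <- with_reference(clean_spectra(comps), rep(42, 10))
  model <- fit_pls(sp, preprocess_chain(character(0)), n_factors = 2)
  expect_equal(predict(model, sp), rep(42, 10), tolerance = 1e-8)
})

test_that("PLS is invariant to sample order", {
  comps <- simulate_components(15, seed = 6)
  sp <- with_reference(clean_spectra(comps), comps$lignin)
  m1 <- fit_pls(sp, n_factors = 3)
  perm <- c(4, 1, 15, 7, 2, 9, 3, 14, 6, 11, 5, 13, 8, 10, 12)
  m2 <- fit_pls(spectra_subset(sp, perm), n_factors = 3)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
})

test_that("full-rank PLS predictions agree with ordinary least squares", {
  # p < n: with all factors retained PLS spans the predictor space, so its
  # fitted values must coincide with the multiple-regression fit
  set.seed(7)
  n <- 20; p <- 6
  X <- matrix(stats::rnorm(n * p), n)
  y <- drop(X %*% stats::runif(p, -1, 1)) + stats::rnorm(n, sd = 0.1)
  core <- fiberGM:::pls1_core(X, y, n_factors = p)
  fitted_pls <- drop(X %*% core$coefficients) + core$intercept
  fitted_ols <- stats::fitted(stats::lm(y ~ X))
  expect_equal(fitted_pls, unname(fitted_ols), tolerance = 1e-8)
})

test_that("leave-one-out predictions equal the brute-force refit oracle", {
  comps <- simulate_components(12, seed = 8)
  sp <- simulate_spectra(comps, grid = seq(4000, 9000, by = 50), seed = 8)
  sp <- with_reference(sp, comps$cellulose)
  chain <- preprocess_chain()
  cv <- cross_validate(sp, chain, n_factors = 3)
  oracle <- vapply(seq_len(12), function(i) {
    m <- fit_pls(spectra_subset(sp, setdiff(1:12, i)), chain, 3)
    predict(m, spectra_subset(sp, i))
  }, numeric(1))
  expect_equal(cv$cv_predictions, oracle, tolerance = 1e-10)
})

test_that("noise-free identifiable mixtures cross-validate near perfectly", {
  comps <- simulate_components(16, seed = 9)
  sp <- with_reference(clean_spectra(comps), comps$hemicellulose)
  cv <- cross_validate(sp, preprocess_chain(character(0)), n_factors = 3)
  expect_gt(cv$r2cv, 0.999)
})

test_that("uninformative predictors give unclamped non-positive cv-R2", {
  set.seed(10)
  grid <- seq(4000, 6000, by = 20)
  X <- matrix(stats::rnorm(14 * length(grid)), 14)
  sp <- spectra_set(grid, X, reference = stats::rnorm(14))
  cv <- cross_validate(sp, preprocess_chain(character(0)), n_factors = 2)
  expect_lte(cv$r2cv, 0)
})

test_that("factor selection finds the mixture rank and respects bounds", {
  comps <- simulate_components(16, structure = "independent", seed = 11)
  sp <- with_reference(clean_spectra(comps), comps$cellulose)
  expect_equal(select_factors(sp, preprocess_chain(character(0)),
                              max_factors = 6), 3)
  # single-component data: one factor suffices
  single <- comps
  single$hemicellulose <- 0 * single$hemicellulose
  single$lignin <- 0 * single$lignin
  sp1 <- with_reference(clean_spectra(single), single$cellulose)
  expect_equal(select_factors(sp1, preprocess_chain(character(0)),
                              max_factors = 4), 1)
})

test_that("validation t-test reproduces the printed statistics exactly", {
  val <- load_validation()
  printed <- c(cellulose = 0.019, hemicellulose = 0.378, lignin = 1.500)
  for (cc in names(printed)) {
    sub <- val[val$component == cc, ]
    tt <- validation_ttest(sub$measured, sub$predicted)
    expect_equal(round(tt$t_abs, 3), printed[[cc]])
    expect_false(tt$significant)
    expect_equal(round(tt$t_critical, 3), 4.303)
    expect_equal(tt$abs_error, abs(sub$measured - sub$predicted))
  }
})

test_that("t-test edge cases and oracle agreement hold", {
  same <- c(10, 20, 30)
  tt <- validation_ttest(same, same)
  expect_equal(tt$t_abs, 0)
  expect_false(tt$significant)
  shifted <- validation_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(shifted$t_abs, Inf)
  expect_true(shifted$significant)
  set.seed(13)
  for (i in 1:25) {
    m <- stats::runif(3, 0, 100)
    p <- m + stats::rnorm(3)
    expect_equal(validation_ttest(m, p)$t_abs, ttest_oracle(m, p),
                 tolerance = 1e-12)
  }
  expect_error(validation_ttest(1, 2), "at least 2")
})

test_that("preprocessing chain does not hurt calibration on default spectra", {
  res <- vapply(1:3, function(s) {
    comps <- simulate_components(22, seed = s)
    grid <- seq(4000, 9000, by = 20)
    sp <- simulate_spectra(comps, grid = grid, seed = s)
    r2 <- function(chain) {
      mean(vapply(c("cellulose", "hemicellulose", "lignin"), function(cc) {
        cross_validate(with_reference(sp, comps[[cc]]), chain,
                       n_factors = 6)$r2cv
      }, numeric(1)))
    }
    r2(preprocess_chain()) - r2(preprocess_chain(character(0)))
  }, numeric(1))
  expect_true(all(res >= 0))
})

test_that("cross-validated accuracy degrades monotonically with noise", {
  comps <- simulate_components(22, seed = 21)
  grid <- seq(4000, 9000, by = 20)
  r2_at <- function(noise) {
    sp <- simulate_spectra(comps, grid = grid, noise_sd = noise, seed = 21)
    cross_validate(with_reference(sp, comps$cellulose), preprocess_chain(),
                   n_factors = 5)$r2cv
  }
  r2s <- vapply(c(0.002, 0.05, 0.3), r2_at, numeric(1))
  expect_true(all(diff(r2s) < 0))
  expect_gt(r2s[1], 0.95)
})
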