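# Seedable generators emulating the inputs the analysis consumes: component
# profiles spanning the measured composition ranges, Beer-Lambert NIR
# mixture spectra, single-fiber tensile compliance points, and
# exactly-consistent grey systems for round-trip testing. Every generator is
# a pure function of (config, seed): a single seed is expanded into fixed
# per-generator substreams so stages stay reproducible in isolation.

substream <- function(seed, stream) {
  offsets <- c(components = 101L, spectra = 211L, tensile = 307L,
               grey = 401L)
  (as.integer(seed) + offsets[[stream]]) %% .Machine$integer.max
}

#' Default composition ranges for simulation
#'
#' Per-component uniform sampling ranges (\% by mass) spanning the extremes
#' of the measured 26-sample composition table: cellulose 7.93-80.58,
#' hemicellulose 10.33-20.96, lignin 3.94-76.97.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
default_component_ranges <- function() {
  list(cellulose = c(7.93, 80.58),
       hemicellulose = c(10.33, 20.96),
       lignin = c(3.94, 76.97))
}

#' Simulate component composition profiles
#'
#' Generates per-sample cellulose/hemicellulose/lignin contents (\% by
#' mass). The default `"degumming"` structure emulates how the real sample
#' set was produced: a latent degumming degree moves each sample along a
#' trajectory on which lignin is stripped and cellulose correspondingly
#' enriched (the two are almost perfectly anti-correlated in the measured
#' table), while hemicellulose varies independently within its observed
#' range; small Gaussian noise represents wet-chemistry measurement error.
#' The `"independent"` structure draws each content uniformly within its
#' range instead, for stress-testing calibrations on unstructured
#' compositions. Both structures rejection-resample rows until every content
#' lies inside its range and the three contents sum to at most 100\% (they
#' never account for the whole mass, but cannot exceed it).
#'
#' @param n_samples Number of samples; default 26.
#' @param ranges Named list of `c(min, max)` ranges (\%); default
#'   [default_component_ranges()].
#' @param structure `"degumming"` (default) or `"independent"`.
#' @param noise_sd Measurement noise on each content for the degumming
#'   structure (\% absolute); default 0.3.
#' @param seed Integer seed.
#' @return Data frame with columns `sample_id`, `cellulose`,
#'   `hemicellulose`, `lignin`.
#' @export
simulate_components <- function(n_samples = 26,
                                ranges = default_component_ranges(),
                                structure = c("degumming", "independent"),
                                noise_sd = 0.3,
                                seed = 1) {
  structure <- match.arg(structure)
  stopifnot(n_samples >= 1,
            all(c("cellulose", "hemicellulose", "lignin") %in% names(ranges)))
  lows <- vapply(ranges, `[`, numeric(1), 1)
  highs <- vapply(ranges, `[`, numeric(1), 2)
  if (any(highs < lows)) stop("invalid range: max < min", call. = FALSE)
  if (sum(lows) > 100) {
    stop("infeasible ranges: minimum contents already exceed 100%",
         call. = FALSE)
  }
  draw_row <- if (structure == "independent") {
    function() {
      repeat {
        v <- stats::runif(3, lows, highs)
        if (sum(v) <= 100) return(v)
      }
    }
  } else {
    # degumming trajectory: endpoints chosen so the noise-free curve spans
    # the observed cellulose (8.0 -> 80.5) and lignin (76.5 -> 4.2) extremes
    function() {
      repeat {
        d <- stats::runif(1)
        h <- stats::runif(1, lows[["hemicellulose"]],
                          highs[["hemicellulose"]])
        v <- c(8.0 + 72.5 * d, h, 76.5 - 72.3 * d) +
          stats::rnorm(3, 0, noise_sd)
        if (all(v >= lows) && all(v <= highs) && sum(v) <= 100) return(v)
      }
    }
  }
  with_seed(substream(seed, "components"), {
    m <- t(vapply(seq_len(n_samples), function(i) draw_row(), numeric(3)))
    data.frame(sample_id = seq_len(n_samples),
               cellulose = m[, 1], hemicellulose = m[, 2], lignin = m[, 3])
  })
}

#' Default pure-component NIR band models
#'
#' Gaussian band sets (center cm^-1, width as Gaussian sd, intensity in AU
#' per \% content) for the three components, placed in the 4,000-9,000 cm^-1
#' overtone/combination region with deliberate overlap between components so
#' that the simulated mixture-calibration problem is neither trivial nor
#' degenerate. These are generic lignocellulose-like band sets for
#' simulation, not assignments of measured bands.
#'
#' @return Named list of data frames with columns `center`, `width`,
#'   `intensity`.
#' @export
default_band_sets <- function() {
  list(
    cellulose = data.frame(
      center = c(4280, 4760, 5200, 5800, 6720, 8400),
      width = c(60, 80, 90, 110, 120, 160),
      intensity = c(0.008, 0.010, 0.012, 0.006, 0.009, 0.004)),
    hemicellulose = data.frame(
      center = c(4390, 4900, 5180, 5980, 7000),
      width = c(70, 90, 100, 120, 150),
      intensity = c(0.009, 0.011, 0.008, 0.007, 0.005)),
    lignin = data.frame(
      center = c(4680, 5100, 5560, 6250, 6900, 8100),
      width = c(65, 85, 95, 130, 140, 170),
      intensity = c(0.010, 0.007, 0.011, 0.008, 0.006, 0.003)))
}

pure_spectrum <- function(grid, bands) {
  out <- numeric(length(grid))
  for (j in seq_len(nrow(bands))) {
    out <- out + bands$intensity[j] *
      exp(-0.5 * ((grid - bands$center[j]) / bands$width[j])^2)
  }
  out
}

#' Simulate NIR absorbance spectra from composition profiles
#'
#' Beer-Lambert mixture model: each spectrum is the content-weighted sum of
#' the pure-component band models, degraded by a per-sample linear baseline,
#' per-sample multiplicative scatter and iid additive Gaussian noise:
#' `A(v) = scatter * sum_i content_i * pure_i(v) + offset + slope * v + noise`.
#'
#' @param components Data frame with columns `cellulose`, `hemicellulose`,
#'   `lignin` (\%), e.g. from [simulate_components()].
#' @param grid Wavenumber grid (cm^-1); default `seq(4000, 12000, by = 4)`.
#' @param bands Named list of band tables; default [default_band_sets()].
#'   Every component must have at least one band.
#' @param baseline_offset,baseline_slope Ranges `c(min, max)` of the
#'   per-sample additive baseline: offset in AU, slope in AU per cm^-1.
#'   Defaults span the baseline magnitudes typical of diffuse-reflectance
#'   powder spectra.
#' @param scatter Range of the per-sample multiplicative scatter factor;
#'   the default +-30\% reflects particle-size-driven scatter in powder
#'   spectra, the artifact SNV is designed to correct.
#' @param noise_sd Standard deviation of the additive noise (AU).
#' @param seed Integer seed.
#' @return A [spectra_set()] whose `reference` is unset; attach the target
#'   component's contents before calibration.
#' @export
simulate_spectra <- function(components,
                             grid = seq(4000, 12000, by = 4),
                             bands = default_band_sets(),
                             baseline_offset = c(0, 0.3),
                             baseline_slope = c(-2e-5, 2e-5),
                             scatter = c(0.7, 1.3),
                             noise_sd = 0.002,
                             seed = 1) {
  comps <- c("cellulose", "hemicellulose", "lignin")
  stopifnot(all(comps %in% names(components)), all(comps %in% names(bands)))
  if (any(vapply(bands[comps], nrow, integer(1)) == 0)) {
    stop("every component needs at least one band", call. = FALSE)
  }
  pures <- vapply(comps, function(cc) pure_spectrum(grid, bands[[cc]]),
                  numeric(length(grid)))
  n <- nrow(components)
  content <- as.matrix(components[, comps])
  signal_mat <- content %*% t(pures)   # n x p, Beer-Lambert superposition
  with_seed(substream(seed, "spectra"), {
    off <- stats::runif(n, baseline_offset[1], baseline_offset[2])
    slp <- stats::runif(n, baseline_slope[1], baseline_slope[2])
    sc <- stats::runif(n, scatter[1], scatter[2])
    noise <- matrix(stats::rnorm(n * length(grid), sd = noise_sd), n)
    A <- sc * signal_mat + off + outer(slp, grid) + noise
    spectra_set(grid, A, sample_ids = components$sample_id)
  })
}

#' Simulate single-fiber tensile compliance points
#'
#' Emulates the published test design: for each gauge length and replicate,
#' draws a fiber cross-sectional area (lognormal) and produces a point on
#' the compliance line, `dl_over_f = l0_over_a / true_e + true_cs + noise`.
#' Defaults follow the published protocol of three gauge lengths (20, 30,
#' 40 mm) with 15 tests each, i.e. 45 points per sample.
#'
#' @param true_e True Young's modulus, MPa (> 0); default 1500.
#' @param true_cs True system compliance, mm/N; default 0.2.
#' @param gauge_lengths Gauge lengths in mm; default `c(20, 30, 40)`.
#' @param n_per_length Replicates per gauge length; default 15.
#' @param area_meanlog,area_sdlog Lognormal parameters of the fiber
#'   cross-sectional area (mm^2); defaults give a median near 0.08 mm^2,
#'   typical of coarse palm fibers.
#' @param noise_sd Gaussian noise sd on `dl_over_f` (mm/N); default 0.02.
#' @param seed Integer seed.
#' @return Data frame with columns `gauge_length_mm`, `area_mm2`,
#'   `l0_over_a`, `dl_over_f`.
#' @export
simulate_tensile <- function(true_e = 1500, true_cs = 0.2,
                             gauge_lengths = c(20, 30, 40),
                             n_per_length = 15,
                             area_meanlog = log(0.08), area_sdlog = 0.25,
                             noise_sd = 0.02, seed = 1) {
  stopifnot(true_e > 0, all(gauge_lengths > 0), n_per_length >= 1)
  with_seed(substream(seed, "tensile"), {
    l0 <- rep(gauge_lengths, each = n_per_length)
    area <- stats::rlnorm(length(l0), area_meanlog, area_sdlog)
    l0_over_a <- l0 / area
    dl_over_f <- l0_over_a / true_e + true_cs +
      stats::rnorm(length(l0), sd = noise_sd)
    data.frame(gauge_length_mm = l0, area_mm2 = area,
               l0_over_a = l0_over_a, dl_over_f = dl_over_f)
  })
}

#' Simulate an exactly-consistent grey system
#'
#' Forward-generates a reference series satisfying the grey differential
#' equation exactly (noise-free) for given coefficients and comparative
#' series. With the consecutive-pair mean convention, the defining equation
#' can be solved for the reference increment at each k:
#' `X0(k) = (sum_i b_i * Xi_ago(k) - a * X0_ago(k-1)) / (1 + a/2)`,
#' starting from an initialized value of 1 at k = 1. Optional Gaussian noise
#' is then added to the reference series (k >= 2).
#'
#' @param n Sequence length; default 15.
#' @param coefficients List with `a` and `b` (numeric vector, one per
#'   comparative series). `1 + a/2` must be nonzero. Default: the published
#'   GM(1,4) coefficients.
#' @param comparatives Optional list of positive raw comparative series of
#'   length `n`; by default `length(coefficients$b)` series are drawn as
#'   cumulative products of lognormal steps (positive, mildly trending).
#' @param noise_sd Observation noise sd on the initialized reference values
#'   at k >= 2; default 0 (exact system).
#' @param seed Integer seed.
#' @return List with `reference` (raw series, first element 1),
#'   `comparatives` (list of raw series), `coefficients`.
#' @export
simulate_grey_system <- function(n = 15,
                                 coefficients = list(a = 0.3129,
                                                     b = c(0.5292, -0.9558,
                                                           1.1413)),
                                 comparatives = NULL,
                                 noise_sd = 0, seed = 1) {
  a <- coefficients$a
  b <- coefficients$b
  if (abs(1 + a / 2) < 1e-12) {
    stop("forward recursion undefined: 1 + a/2 = 0", call. = FALSE)
  }
  with_seed(substream(seed, "grey"), {
    if (is.null(comparatives)) {
      comparatives <- lapply(seq_along(b), function(i) {
        exp(cumsum(stats::rnorm(n, mean = 0.05, sd = 0.15)))
      })
    }
    stopifnot(length(comparatives) == length(b),
              all(vapply(comparatives, length, integer(1)) == n),
              all(unlist(comparatives) > 0))
    ago_mat <- vapply(comparatives,
                      function(s) grey_ago(grey_initialize(s)),
                      numeric(n))
    x0 <- numeric(n)
    x0[1] <- 1
    cum <- 1
    for (k in 2:n) {
      x0[k] <- (sum(b * ago_mat[k, ]) - a * cum) / (1 + a / 2)
      cum <- cum + x0[k]
    }
    if (noise_sd > 0) {
      x0[-1] <- x0[-1] + stats::rnorm(n - 1, sd = noise_sd)
    }
    list(reference = x0, comparatives = comparatives,
         coefficients = coefficients)
  })
}
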