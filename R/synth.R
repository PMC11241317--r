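#' Configuration for the synthetic spectra generator
#'
#' The generator emulates transmittance micro-spectra of pigmented tissue:
#' a smooth polynomial baseline multiplied by a Beer-Lambert attenuation
#' term with Gaussian absorbance bands whose depth scales with anthocyanin
#' concentration, a per-spectrum log-normal scatter factor, per-spectrum
#' polynomial baseline drift, and i.i.d. additive noise:
#'
#' \deqn{T(\lambda) = 100 \, B(\lambda)\,(1 + d(\lambda))\, s\,
#'   \exp\{-f(c) \sum_k g_k \, e^{-(\lambda-\mu_k)^2 / 2\sigma_k^2}\}
#'   + \epsilon(\lambda)}
#'
#' Default absorption bands sit at 530, 700 and 850 nm -- the visible
#' anthocyanin/pigment dips plus the third C-H overtone region -- and the
#' default concentration range (uniform on 0.6--4.0 %) gives the targets a
#' standard deviation of about 0.98 %.
#'
#' @param n_samples samples per generated dataset (default 576, one tissue).
#' @param peak_centers,peak_widths,peak_gains Gaussian absorbance band
#'   centers (nm), SDs (nm) and per-unit-concentration gains; equal length.
#' @param concentration_range interval (in % content units) targets are
#'   drawn from, uniformly.
#' @param baseline_order polynomial order of the baseline and of the
#'   per-spectrum drift term.
#' @param baseline_drift_sd SD of the per-spectrum random drift polynomial
#'   coefficients (relative units); 0 disables drift.
#' @param conc_noise_sd SD (in % units) of sample-level concentration noise:
#'   the spectrum reflects a perturbed effective concentration, emulating
#'   biological variability and reference-method error that decouple the
#'   optical signal from the reference value. This sets the irreducible
#'   prediction error floor; the default 0.35 puts full-spectrum PLS in the
#'   RMSEP ~0.4 / RPD ~2.5 regime typical of tissue calibration studies.
#' @param scatter_sd SD of the log scatter factor (multiplicative,
#'   log-normal); 0 disables scatter.
#' @param noise_sd SD of additive band noise, in transmittance points.
#' @param link concentration-absorbance link: `"linear"` (f(c) = c) or
#'   `"quadratic"` (f(c) = c + link_quad * c^2).
#' @param link_quad curvature of the quadratic link.
#' @param seed integer seed used by [generate_dataset()].
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_samples = 576L,
                         peak_centers = c(530, 700, 850),
                         peak_widths = c(15, 25, 20),
                         peak_gains = c(0.15, 0.10, 0.08),
                         concentration_range = c(0.6, 4.0),
                         baseline_order = 2L,
                         baseline_drift_sd = 0.005,
                         conc_noise_sd = 0.35,
                         scatter_sd = 0.02,
                         noise_sd = 0.3,
                         link = c("linear", "quadratic"),
                         link_quad = 0.25,
                         seed = 1L) {
  link <- match.arg(link)
  stopifnot(
    length(peak_centers) == length(peak_widths),
    length(peak_centers) == length(peak_gains),
    all(peak_widths > 0),
    length(concentration_range) == 2,
    concentration_range[1] < concentration_range[2],
    concentration_range[1] >= 0,
    noise_sd >= 0, scatter_sd >= 0, baseline_drift_sd >= 0,
    conc_noise_sd >= 0, baseline_order >= 0
  )
  structure(
    list(
      n_samples = as.integer(n_samples),
      peak_centers = peak_centers, peak_widths = peak_widths,
      peak_gains = peak_gains,
      concentration_range = concentration_range,
      baseline_order = as.integer(baseline_order),
      baseline_drift_sd = baseline_drift_sd,
      conc_noise_sd = conc_noise_sd,
      scatter_sd = scatter_sd, noise_sd = noise_sd,
      link = link, link_quad = link_quad,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generator settings for the nonlinear model-comparison study
#'
#' A named condition set for contrasting the flexible CNN regressor with
#' linear PLS. Two things distinguish it from the default (linear) study:
#' a saturating quadratic concentration-absorbance link, and strong
#' multiplicative scatter plus baseline drift left in the raw spectra.
#' The interference matters: with clean spectra the many-band exponential
#' attenuation family is rich enough for a linear model to invert even a
#' curved link essentially perfectly, so a nonlinear-advantage study run
#' there would measure nothing. Under realistic raw-spectrum interference
#' the convolutional model's local feature extraction pays off.
#'
#' @param n_samples,seed forwarded to [synth_config()].
#' @return a [synth_config()] with the nonlinear study conditions.
#' @export
nonlinear_study_config <- function(n_samples = 300L, seed = 11L) {
  synth_config(n_samples = n_samples, link = "quadratic", link_quad = 0.25,
               scatter_sd = 0.15, baseline_drift_sd = 0.03,
               conc_noise_sd = 0.05, seed = seed)
}

# smooth transmittance baseline in (0.5, 1): quadratic in scaled wavelength
synth_baseline <- function(grid) {
  u <- scale_unit(grid$band_centers)
  0.85 - 0.10 * u - 0.10 * u^2
}

# effective absorbance multiplier as a function of concentration
synth_link <- function(concentration, config) {
  if (config$link == "quadratic") {
    concentration + config$link_quad * concentration^2
  } else {
    concentration
  }
}

# total Gaussian absorbance profile at unit link value
synth_absorbance_profile <- function(grid, config) {
  lambda <- grid$band_centers
  prof <- numeric(length(lambda))
  for (k in seq_along(config$peak_centers)) {
    prof <- prof + config$peak_gains[k] *
      exp(-(lambda - config$peak_centers[k])^2 / (2 * config$peak_widths[k]^2))
  }
  prof
}

#' Generate one synthetic transmittance spectrum
#'
#' Draws the random components (concentration noise, drift, scatter, band
#' noise) from the current RNG state; with `conc_noise_sd`,
#' `baseline_drift_sd`, `scatter_sd` and `noise_sd` all zero the output is
#' a deterministic function of the concentration.
#'
#' @param concentration anthocyanin content in % units; must be >= 0.
#' @param grid a [wavelength_grid()].
#' @param config a [synth_config()].
#' @return numeric vector of transmittance values (%), length of the grid.
#' @export
generate_spectrum <- function(concentration, grid = wavelength_grid(),
                              config = synth_config()) {
  stopifnot_grid(grid)
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      !is.finite(concentration) || concentration < 0) {
    stop("`concentration` must be a single finite value >= 0 (% units)")
  }
  p <- length(grid)
  base <- synth_baseline(grid)
  c_eff <- if (config$conc_noise_sd > 0) {
    max(0, concentration + stats::rnorm(1, 0, config$conc_noise_sd))
  } else {
    concentration
  }
  drift <- if (config$baseline_drift_sd > 0) {
    u <- scale_unit(grid$band_centers)
    coef <- stats::rnorm(config$baseline_order + 1L, 0, config$baseline_drift_sd)
    drop(outer(u, 0:config$baseline_order, `^`) %*% coef)
  } else {
    numeric(p)
  }
  s <- if (config$scatter_sd > 0) exp(stats::rnorm(1, 0, config$scatter_sd)) else 1
  absorb <- synth_link(c_eff, config) * synth_absorbance_profile(grid, config)
  eps <- if (config$noise_sd > 0) stats::rnorm(p, 0, config$noise_sd) else numeric(p)
  100 * base * (1 + drift) * s * exp(-absorb) + eps
}

#' Generate a synthetic spectra + concentration dataset
#'
#' Reproduces the shape of the study design this package targets: by
#' default a 576 x 616 transmittance matrix with a matched anthocyanin
#' target vector. The returned `truth` element records the generator
#' parameters and the informative band indices (within +/- 2 SD of each
#' absorption peak center).
#'
#' @param config a [synth_config()]; `config$seed` fixes all randomness.
#' @param grid a [wavelength_grid()].
#' @param tissue,variety metadata labels attached to the spectrum matrix.
#' @return A `synthetic_dataset` list: `spectra` (a [spectrum_matrix()]),
#'   `targets` (numeric, % units), `truth`.
#' @examples
#' ds <- generate_dataset(synth_config(n_samples = 40, seed = 7))
#' dim(ds$spectra$values)  # 40 x 616
#' @export
generate_dataset <- function(config = synth_config(), grid = wavelength_grid(),
                             tissue = "inner", variety = "synthetic") {
  stopifnot_grid(grid)
  n <- config$n_samples
  if (n < 10L) stop("n_samples must be >= 10 (smaller sets cannot be split)")
  set.seed(config$seed)
  targets <- stats::runif(n, config$concentration_range[1], config$concentration_range[2])
  p <- length(grid)
  values <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    values[i, ] <- generate_spectrum(targets[i], grid, config)
  }
  ids <- sprintf("S%04d", seq_len(n))
  informative <- sort(unique(unlist(lapply(seq_along(config$peak_centers), function(k) {
    which(abs(grid$band_centers - config$peak_centers[k]) <= 2 * config$peak_widths[k])
  }))))
  structure(
    list(
      spectra = spectrum_matrix(values, grid, sample_ids = ids,
                                tissue = tissue, variety = variety),
      targets = targets,
      truth = list(informative_bands = informative, config = config)
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d spectra x %d bands; target SD %.3f %%; %d informative bands\n",
    nrow(x$spectra$values), ncol(x$spectra$values),
    stats::sd(x$targets), length(x$truth$informative_bands)
  ))
  invisible(x)
}

#' Generate a raw hypercube with matched black and white reference frames
#'
#' Builds the three frames an imaging spectrometer produces: a dark frame
#' (lens capped), a white reference, and a raw cube satisfying
#' `raw = black + (white - black) * T / 100` per pixel and band, where `T`
#' is a [generate_spectrum()] draw plus per-pixel spatial noise. The black
#' frame is strictly below the white frame everywhere, so black/white
#' calibration of the raw cube recovers `T`.
#'
#' @param concentration anthocyanin content (% units) of the simulated sample.
#' @param lines,pixels spatial cube dimensions; at least 100 x 100 is needed
#'   to host the standard ROI.
#' @param grid,config as in [generate_spectrum()].
#' @param pixel_noise_sd SD of i.i.d. per-pixel transmittance noise (points).
#' @param dark_level,white_level mean digital-number levels of the frames.
#' @param texture amplitude of a deterministic spatial pattern added to both
#'   reference frames (mimics fixed-pattern response).
#' @param band_profile if `TRUE`, the white frame carries a smooth spectral
#'   lamp profile; `FALSE` gives flat references.
#' @return list with `raw`, `black`, `white` [hypercube()] objects and the
#'   noiseless `spectrum` used.
#' @export
generate_cube_with_references <- function(concentration, lines = 120L, pixels = 120L,
                                          grid = wavelength_grid(), config = synth_config(),
                                          pixel_noise_sd = 0.5,
                                          dark_level = 100, white_level = 4000,
                                          texture = 2, band_profile = TRUE) {
  stopifnot_grid(grid)
  lines <- as.integer(lines); pixels <- as.integer(pixels)
  if (lines < 1L || pixels < 1L) stop("`lines` and `pixels` must be >= 1")
  if (white_level <= dark_level) stop("white_level must exceed dark_level")
  p <- length(grid)

  spec <- generate_spectrum(concentration, grid, config)

  pattern <- if (texture > 0) {
    outer(seq_len(lines), seq_len(pixels), function(i, j) texture * ((i + j) %% 5) / 5)
  } else {
    matrix(0, lines, pixels)
  }
  lamp <- if (band_profile) 0.85 + 0.15 * synth_baseline(grid) else rep(1, p)

  black <- array(rep(pattern, p) + dark_level, dim = c(lines, pixels, p))
  white <- array(rep(pattern, p), dim = c(lines, pixels, p)) +
    rep(white_level * lamp, each = lines * pixels)

  t_pix <- array(rep(spec, each = lines * pixels), dim = c(lines, pixels, p))
  if (pixel_noise_sd > 0) {
    t_pix <- t_pix + array(stats::rnorm(lines * pixels * p, 0, pixel_noise_sd),
                           dim = c(lines, pixels, p))
  }
  raw <- black + (white - black) * t_pix / 100

  list(
    raw = hypercube(raw, grid, kind = "raw"),
    black = hypercube(black, grid, kind = "black"),
    white = hypercube(white, grid, kind = "white"),
    spectrum = spec
  )
}
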