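# shared fixtures: everything is generated in code, sized for speed

# small wavelength grid covering the visible pigment dips
small_grid <- function(p = 64L) wavelength_grid(p, 365, 1025)

# fully deterministic generator settings (all random components off)
noiseless_config <- function(...) {
  synth_config(baseline_drift_sd = 0, conc_noise_sd = 0,
               scatter_sd = 0, noise_sd = 0, ...)
}

# quick random spectrum_matrix fixture
random_spectra <- function(n = 12, p = 64, seed = 1) {
  set.seed(seed)
  g <- small_grid(p)
  spectrum_matrix(matrix(stats::runif(n * p, 40, 90), n, p), g)
}

# dataset with a handful of informative bands in pure noise, for the
# selector recovery studies: y depends on bands `informative` only
sparse_signal_data <- function(n, p, informative = NULL, snr = 20,
                               seed = 1) {
  if (is.null(informative)) informative <- as.integer(c(p %/% 4, (3 * p) %/% 4))
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  beta <- numeric(p)
  beta[informative] <- c(1, -1)[seq_along(informative) %% 2 + 1]
  signal <- drop(X %*% beta)
  y <- signal + stats::rnorm(n, 0, stats::sd(signal) / snr)
  list(X = X, y = y, informative = informative)
}
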