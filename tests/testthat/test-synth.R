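test_that("zero concentration with all noise off returns the pure baseline", {
  g <- small_grid()
  cfg <- noiseless_config()
  s <- generate_spectrum(0, g, cfg)
  base <- 100 * anthospec:::synth_baseline(g)
  expect_equal(s, base, tolerance = 0)
  expect_true(all(base >= 50 & base <= 100))
})

test_that("transmittance at the pigment dips decreases with concentration", {
  g <- wavelength_grid()
  cfg <- noiseless_config()
  s1 <- generate_spectrum(1, g, cfg)
  s2 <- generate_spectrum(3, g, cfg)
  for (peak in cfg$peak_centers) {
    j <- which.min(abs(g$band_centers - peak))
    expect_lt(s2[j], s1[j])
  }
  # equal concentrations give identical noiseless spectra
  expect_identical(generate_spectrum(2, g, cfg), generate_spectrum(2, g, cfg))
})

test_that("spectrum generation is seeded-deterministic and rejects bad doses", {
  g <- small_grid()
  cfg <- synth_config()
  set.seed(99); a <- generate_spectrum(2, g, cfg)
  set.seed(99); b <- generate_spectrum(2, g, cfg)
  expect_identical(a, b)
  set.seed(100); d <- generate_spectrum(2, g, cfg)
  expect_false(identical(a, d))
  expect_error(generate_spectrum(-0.1, g, cfg), ">= 0")
})

test_that("default dataset reproduces the study shape and target spread", {
  ds <- generate_dataset(synth_config(seed = 4))
  expect_identical(dim(ds$spectra$values), c(576L, 616L))
  expect_length(ds$targets, 576L)
  # uniform on [0.6, 4.0] has SD 3.4/sqrt(12) ~ 0.9815; allow Monte-Carlo slack
  expect_lt(abs(stats::sd(ds$targets) - 3.4 / sqrt(12)), 0.1)
  # truth holds exactly the bands within +/- 2 peak widths of each center
  cfg <- ds$truth$config
  expected <- sort(unique(unlist(lapply(seq_along(cfg$peak_centers), function(k) {
    which(abs(ds$spectra$grid$band_centers - cfg$peak_centers[k]) <=
            2 * cfg$peak_widths[k])
  }))))
  expect_identical(ds$truth$informative_bands, expected)
})

test_that("datasets are reproducible by seed and reject tiny n", {
  c1 <- synth_config(n_samples = 20, seed = 7)
  expect_identical(generate_dataset(c1, small_grid())$spectra$values,
                   generate_dataset(c1, small_grid())$spectra$values)
  c2 <- synth_config(n_samples = 20, seed = 8)
  expect_false(identical(generate_dataset(c1, small_grid())$targets,
                         generate_dataset(c2, small_grid())$targets))
  expect_error(generate_dataset(synth_config(n_samples = 5), small_grid()),
               ">= 10")
})

test_that("target correlates negatively with transmittance at every peak", {
  cfg <- noiseless_config(n_samples = 60, seed = 3)
  ds <- generate_dataset(cfg, small_grid(128))
  g <- ds$spectra$grid
  for (peak in cfg$peak_centers) {
    j <- which.min(abs(g$band_centers - peak))
    expect_lt(stats::cor(ds$targets, ds$spectra$values[, j]), 0)
  }
})

test_that("generated cubes calibrate back to the generating spectrum", {
  g <- small_grid(40)
  cfg <- noiseless_config()
  # noise-free round trip is exact
  set.seed(5)
  cb <- generate_cube_with_references(2, lines = 30, pixels = 30, g, cfg,
                                      pixel_noise_sd = 0)
  cal <- calibrate_cube(cb$raw, cb$black, cb$white)
  m <- extract_roi_mean(cal, roi_spec(0, 0, 30, 30))
  expect_equal(m, cb$spectrum, tolerance = 1e-10)
  # flat identity references make raw equal transmittance
  cb2 <- generate_cube_with_references(1, 20, 20, g, cfg, pixel_noise_sd = 0,
                                       dark_level = 0, white_level = 100,
                                       texture = 0, band_profile = FALSE)
  expect_equal(cb2$raw$data[3, 7, ], cb2$spectrum, tolerance = 1e-10)
  expect_true(all(cb2$black$data < cb2$white$data))
})

test_that("ROI averaging shrinks pixel noise like 1/sqrt(pixels)", {
  g <- small_grid(40)
  set.seed(11)
  cb <- generate_cube_with_references(2, 100, 100, g, noiseless_config(),
                                      pixel_noise_sd = 2)
  cal <- calibrate_cube(cb$raw, cb$black, cb$white)
  m <- extract_roi_mean(cal, roi_spec(0, 0, 100, 100))
  dev <- m - cb$spectrum
  # per-band SE of a 10,000-pixel mean at sigma = 2 is 0.02
  expect_lt(stats::sd(dev), 3 * 0.02)
  expect_gt(stats::sd(dev), 0.02 / 3)
})

test_that("cube generation validates its geometry", {
  g <- small_grid(8)
  expect_error(generate_cube_with_references(1, 0, 10, g), ">= 1")
  expect_error(
    generate_cube_with_references(1, 10, 10, g, white_level = 50, dark_level = 60),
    "exceed")
})
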