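make_cubes <- function(p = 6, lines = 4, pixels = 5) {
  g <- small_grid(p)
  b <- hypercube(array(100, c(lines, pixels, p)), g, "black")
  w <- hypercube(array(4000, c(lines, pixels, p)), g, "white")
  list(g = g, b = b, w = w, dims = c(lines, pixels, p))
}

test_that("calibration maps the reference frames to 0, 100 and midpoints", {
  cc <- make_cubes()
  r_w <- hypercube(cc$w$data, cc$g, "raw")
  expect_equal(calibrate_cube(r_w, cc$b, cc$w)$data,
               array(100, cc$dims), tolerance = 1e-12)
  r_b <- hypercube(cc$b$data, cc$g, "raw")
  expect_equal(calibrate_cube(r_b, cc$b, cc$w)$data,
               array(0, cc$dims), tolerance = 1e-12)
  r_m <- hypercube((cc$b$data + cc$w$data) / 2, cc$g, "raw")
  expect_equal(calibrate_cube(r_m, cc$b, cc$w)$data,
               array(50, cc$dims), tolerance = 1e-12)
})

test_that("calibration is invariant under affine re-gauging of the frames", {
  cc <- make_cubes()
  set.seed(2)
  raw <- hypercube(array(stats::runif(prod(cc$dims), 100, 4000), cc$dims),
                   cc$g, "raw")
  c0 <- calibrate_cube(raw, cc$b, cc$w)
  a <- 3.7; off <- 250
  c1 <- calibrate_cube(hypercube(a * raw$data + off, cc$g, "raw"),
                       hypercube(a * cc$b$data + off, cc$g, "black"),
                       hypercube(a * cc$w$data + off, cc$g, "white"))
  expect_equal(c1$data, c0$data, tolerance = 1e-10)
})

test_that("degenerate pixels become NA and are excluded from ROI means", {
  cc <- make_cubes(p = 4, lines = 12, pixels = 12)
  raw <- hypercube(array(2000, c(12, 12, 4)), cc$g, "raw")
  black <- array(100, c(12, 12, 4)); white <- array(4000, c(12, 12, 4))
  white[1, 1, 2] <- 50  # one dead pixel in band 2
  expect_warning(
    cal <- calibrate_cube(raw, hypercube(black, cc$g, "black"),
                          hypercube(white, cc$g, "white")),
    "white <= black")
  expect_true(is.na(cal$data[1, 1, 2]))
  m <- extract_roi_mean(cal, roi_spec(0, 0, 12, 12), max_invalid_frac = 0.01)
  expect_equal(m[2], (2000 - 100) / (4000 - 100) * 100, tolerance = 1e-10)
  # > 1% invalid pixels in a band aborts
  white2 <- array(4000, c(12, 12, 4)); white2[1:2, 1, 3] <- 50
  expect_warning(cal2 <- calibrate_cube(raw, hypercube(black, cc$g, "black"),
                                        hypercube(white2, cc$g, "white")))
  expect_error(extract_roi_mean(cal2, roi_spec(0, 0, 12, 12)), "invalid ROI pixels")
})

test_that("ROI means are exact on constant and half/half cubes", {
  g <- small_grid(2)
  arr <- array(7, c(6, 6, 2))
  cal <- hypercube(arr, g, "calibrated")
  expect_equal(extract_roi_mean(cal, roi_spec(0, 0, 6, 6)), c(7, 7))
  arr2 <- array(rep(c(2, 4), each = 18), c(6, 6, 2))  # half 2, half 4 per band
  arr2[, , 2] <- arr2[, , 1]
  cal2 <- hypercube(arr2, g, "calibrated")
  expect_equal(extract_roi_mean(cal2, roi_spec(0, 0, 6, 6)), c(3, 3))
})

test_that("ROI means are permutation-invariant and bounds-checked", {
  g <- small_grid(3)
  set.seed(4)
  arr <- array(stats::rnorm(8 * 8 * 3), c(8, 8, 3))
  cal <- hypercube(arr, g, "calibrated")
  perm <- sample(8)
  cal_p <- hypercube(arr[perm, , , drop = FALSE], g, "calibrated")
  expect_equal(extract_roi_mean(cal, roi_spec(0, 0, 8, 8)),
               extract_roi_mean(cal_p, roi_spec(0, 0, 8, 8)))
  expect_error(extract_roi_mean(cal, roi_spec(4, 0, 8, 8)), "top=4")
  expect_error(extract_roi_mean(hypercube(arr, g, "raw"), roi_spec(0, 0, 8, 8)),
               "calibrated")
})

test_that("stack_samples preserves order and validates shapes", {
  g <- small_grid(5)
  vecs <- list(a = 1:5 * 1.0, b = 6:10 * 1.0, c = 11:15 * 1.0)
  sm <- stack_samples(vecs, g, tissue = "outer", variety = "test")
  expect_identical(dim(sm$values), c(3L, 5L))
  expect_identical(sm$sample_ids, c("a", "b", "c"))
  expect_equal(sm$values[2, ], 6:10, ignore_attr = TRUE)
  expect_identical(sm$tissue, "outer")
  one <- stack_samples(list(1:5 * 1.0), g)
  expect_identical(dim(one$values), c(1L, 5L))
  expect_error(stack_samples(list(), g), "nonempty")
  expect_error(stack_samples(list(1:5 * 1.0, 1:4 * 1.0), g), "same length")
})

test_that("ENVI BSQ round trips preserve data and wavelengths", {
  g <- small_grid(7)
  set.seed(9)
  cube <- hypercube(array(stats::runif(3 * 4 * 7, 0, 100), c(3, 4, 7)),
                    g, "calibrated")
  f <- tempfile(fileext = ".bsq")
  # float64 round trip is exact
  write_envi(cube, f, data_type = 5L)
  back <- read_envi(f, kind = "calibrated")
  expect_identical(back$data, cube$data)
  expect_equal(back$grid$band_centers, g$band_centers, tolerance = 1e-9)
  # float32: quantization happens once; successive cycles are bit-stable
  f4 <- tempfile(fileext = ".bsq")
  write_envi(cube, f4, data_type = 4L)
  r1 <- read_envi(f4)
  write_envi(r1, f4, data_type = 4L)
  r2 <- read_envi(f4)
  expect_identical(r1$data, r2$data)
  expect_equal(r1$data, cube$data, tolerance = 1e-5)
})

test_that("ENVI reader handles BIL interleave and uint16 data", {
  g <- small_grid(3)
  lines <- 2L; pixels <- 4L; p <- 3L
  set.seed(3)
  arr <- array(sample(0:65535, lines * pixels * p), c(lines, pixels, p))
  f <- tempfile()
  # hand-write a BIL uint16 file in the documented layout:
  # line slowest, then band, then sample
  flat <- as.integer(aperm(arr, c(2, 3, 1)))
  flat[flat > 32767L] <- flat[flat > 32767L] - 65536L
  con <- file(f, "wb")
  writeBin(flat, con, size = 2L, endian = "little")
  close(con)
  writeLines(c("ENVI", sprintf("samples = %d", pixels),
               sprintf("lines = %d", lines), sprintf("bands = %d", p),
               "data type = 12", "interleave = bil", "byte order = 0",
               paste0("wavelength = {",
                      paste(g$band_centers, collapse = ","), "}")),
             paste0(f, ".hdr"))
  back <- read_envi(f)
  expect_equal(back$data, arr, ignore_attr = TRUE)
  # uint16 BSQ writer round trip
  cube <- hypercube(arr, g, "raw")
  f2 <- tempfile()
  write_envi(cube, f2, data_type = 12L)
  expect_equal(read_envi(f2)$data, arr, ignore_attr = TRUE)
})

test_that("spectra CSV round trips with targets and repeated labels", {
  ds <- generate_dataset(synth_config(n_samples = 12, seed = 2), small_grid(20))
  f <- tempfile(fileext = ".csv")
  write_spectra_csv(ds$spectra, ds$targets, f)
  back <- read_spectra_csv(f, grid = ds$spectra$grid)
  expect_equal(back$spectra$values, ds$spectra$values,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$targets, ds$targets, tolerance = 1e-12)
  expect_identical(back$spectra$sample_ids, ds$spectra$sample_ids)
  header <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_identical(gsub('"', "", header[1]), "sample_id")
  expect_identical(gsub('"', "", header[length(header)]), "anthocyanin_pct")
})
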