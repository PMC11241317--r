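test_that("SNV centers and scales exactly, and is scatter-invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1), tolerance = 1e-12)
  set.seed(1)
  x <- stats::runif(616, 40, 90)
  z <- snv(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(stats::sd(z) - 1), 1e-10)
  expect_equal(snv(3.2 * x + 17), z, tolerance = 1e-10)   # affine invariance
  expect_equal(snv(z), z, tolerance = 1e-10)              # idempotence
  expect_error(snv(rep(5, 10)), "constant")
  expect_error(snv(3), "at least 2")
})

test_that("detrending annihilates polynomials and is an orthogonal projection", {
  g <- small_grid(100)
  u <- anthospec:::scale_unit(g$band_centers)
  quad <- 3 - 2 * u + 5 * u^2
  expect_lt(max(abs(detrend_spectrum(quad, g, 2))), 1e-10)
  expect_lt(max(abs(detrend_spectrum(rep(4, 100), g, 3))), 1e-10)
  set.seed(2)
  x <- stats::rnorm(100)
  d <- detrend_spectrum(x, g, 2)
  # residual orthogonal to the polynomial space
  for (pow in 0:2) expect_lt(abs(sum(d * u^pow)) / sqrt(sum(x^2)), 1e-8)
  expect_equal(detrend_spectrum(d, g, 2), d, tolerance = 1e-10)  # idempotent
  expect_error(detrend_spectrum(x[1:3], small_grid(3), 2), "below length")
})

test_that("detrending a spike matches the explicit least-squares oracle", {
  g <- small_grid(50)
  u <- anthospec:::scale_unit(g$band_centers)
  j <- 17
  spike <- numeric(50); spike[j] <- 1
  x <- 1 + 2 * u - 0.5 * u^2 + spike
  # oracle: residual of the spike after projection onto span{1, u, u^2}
  basis <- cbind(1, u, u^2)
  proj <- basis %*% solve(crossprod(basis), crossprod(basis, spike))
  expect_equal(detrend_spectrum(x, g, 2), spike - drop(proj), tolerance = 1e-8)
})

test_that("Savitzky-Golay reproduces polynomials and the classic 5-point weights", {
  g <- small_grid(60)
  u <- seq_len(60)
  cubic <- 2 + u - 0.03 * u^2 + 4e-4 * u^3
  expect_equal(savgol(cubic, 11, 3), cubic, tolerance = 1e-8)
  # impulse response at an interior point = filter weights; compare with a
  # local least-squares oracle solved from the 5-point design matrix
  x <- numeric(41); x[21] <- 1
  got <- savgol(x, 5, 2)[19:23]
  A <- outer(-2:2, 0:2, `^`)
  w_oracle <- (A %*% solve(crossprod(A), t(A)))[3, ]   # center row
  expect_equal(got, rev(w_oracle), tolerance = 1e-12)
  expect_equal(w_oracle, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
  expect_error(savgol(cubic, 10, 2), "odd")
  expect_error(savgol(cubic, 5, 5), "exceed")
})

test_that("Savitzky-Golay is linear and mean-preserving on noisy signals", {
  set.seed(3)
  x <- stats::rnorm(200); y <- stats::rnorm(200)
  expect_equal(savgol(2 * x + 3 * y, 11, 2),
               2 * savgol(x, 11, 2) + 3 * savgol(y, 11, 2), tolerance = 1e-10)
  sig <- 50 + stats::rnorm(500)
  expect_lt(abs(mean(savgol(sig, 11, 2)) - mean(sig)), 3 / sqrt(500))
})

test_that("pipelines apply in order and cover the seven standard treatments", {
  X <- random_spectra(n = 8, p = 64, seed = 5)
  expect_identical(preprocess(X, preprocess_spec()), X)   # Raw passthrough
  a <- preprocess(X, preprocess_spec(c("sg", "snv")))
  b <- preprocess(X, preprocess_spec(c("snv", "sg")))
  expect_false(isTRUE(all.equal(a$values, b$values)))     # order matters
  for (spec in standard_treatments()) {
    out <- preprocess(X, spec)
    expect_identical(dim(out$values), dim(X$values))
    expect_identical(out$sample_ids, X$sample_ids)
  }
})

test_that("pipeline errors carry the failing row index", {
  X <- random_spectra(n = 4, p = 32, seed = 6)
  X$values[3, ] <- 7  # constant row breaks SNV
  expect_error(preprocess(X, preprocess_spec("snv")), "row 3")
})

test_that("preprocess_spec validates its arguments", {
  expect_error(preprocess_spec("msc"), "drawn from")
  expect_error(preprocess_spec(c("sg", "snv", "det")), "at most two")
  expect_error(preprocess_spec("sg", sg_window = 8), "odd")
  expect_error(preprocess_spec("det", det_order = 0), "det_order")
})
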