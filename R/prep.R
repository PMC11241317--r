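#' Standard normal variate transform
#'
#' Centers a spectrum and scales it to unit sample standard deviation
#' (denominator n - 1), removing additive offsets and multiplicative
#' scatter: `snv(a * x + b) = snv(x)` for any `a > 0`.
#'
#' @param x numeric spectrum vector, length >= 2.
#' @return transformed vector with mean 0 and sample SD 1.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x) {
  if (length(x) < 2) stop("SNV needs at least 2 points")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("SNV is undefined for a constant spectrum (SD = 0)")
  (x - mean(x)) / s
}

#' Polynomial detrending
#'
#' Subtracts the least-squares polynomial baseline of the given order,
#' fitted over the wavelength axis (rescaled to [-1, 1] for conditioning).
#' The residual is orthogonal to all polynomials up to that order, so
#' detrending is idempotent and annihilates exact polynomials.
#'
#' @param x numeric spectrum vector.
#' @param grid a [wavelength_grid()] supplying the axis; length of `x`.
#' @param order polynomial order (>= 0; default 2: offset + slope + curvature).
#' @return the detrended vector (same length).
#' @export
detrend_spectrum <- function(x, grid, order = 2L) {
  stopifnot_grid(grid)
  if (length(x) != length(grid)) stop("spectrum length does not match grid")
  order <- as.integer(order)
  if (order < 0) stop("`order` must be >= 0")
  if (order >= length(x) - 1) stop("`order` must be below length(x) - 1")
  u <- scale_unit(grid$band_centers)
  basis <- outer(u, 0:order, `^`)
  fit <- stats::lm.fit(basis, x)
  fit$residuals
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing: each point is replaced by the
#' value at the window center of the polynomial fitted to its window. At
#' the signal ends the local polynomial is evaluated at the edge positions,
#' so the output keeps full length without padding artifacts. Polynomials
#' of degree <= `polyorder` pass through unchanged.
#'
#' @param x numeric spectrum vector, length >= `window`.
#' @param window odd window length (default 11).
#' @param polyorder fitted polynomial degree, < `window` (default 2).
#' @return the smoothed vector.
#' @export
savgol <- function(x, window = 11L, polyorder = 2L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2 == 0) stop("`window` must be odd")
  if (window <= polyorder) stop("`window` must exceed `polyorder`")
  if (length(x) < window) stop("spectrum shorter than the filter window")
  signal::sgolayfilt(x, p = polyorder, n = window)
}

#' Preprocessing pipeline specification
#'
#' An ordered list of up to two operators drawn from SG (Savitzky-Golay
#' smoothing), SNV and DET (polynomial detrending), covering the seven
#' standard treatments: Raw (empty), SG, SNV, DET, SG+SNV, SG+DET, SNV+DET.
#' Order matters: SG then SNV is not SNV then SG.
#'
#' @param steps character vector, subset of `c("sg", "snv", "det")`, length
#'   0--2, applied in the given order; `character(0)` is the identity (Raw).
#' @param sg_window,sg_polyorder Savitzky-Golay window (odd) and degree.
#' @param det_order detrending polynomial order.
#' @return A `preprocess_spec` object.
#' @export
preprocess_spec <- function(steps = character(0), sg_window = 11L,
                            sg_polyorder = 2L, det_order = 2L) {
  steps <- tolower(as.character(steps))
  if (!all(steps %in% c("sg", "snv", "det"))) {
    stop("steps must be drawn from 'sg', 'snv', 'det'")
  }
  if (length(steps) > 2) stop("at most two preprocessing steps are supported")
  if (anyDuplicated(steps)) stop("steps must be distinct")
  sg_window <- as.integer(sg_window); sg_polyorder <- as.integer(sg_polyorder)
  det_order <- as.integer(det_order)
  if (sg_window %% 2 == 0 || sg_window <= sg_polyorder) {
    stop("sg_window must be odd and exceed sg_polyorder")
  }
  if (det_order < 1) stop("det_order must be >= 1")
  structure(
    list(steps = steps, sg_window = sg_window, sg_polyorder = sg_polyorder,
         det_order = det_order),
    class = "preprocess_spec"
  )
}

#' The seven standard preprocessing treatments
#'
#' @param ... parameters forwarded to [preprocess_spec()] (window, orders).
#' @return named list of `preprocess_spec` objects: Raw, SG, SNV, DET,
#'   SG+SNV, SG+DET, SNV+DET.
#' @export
standard_treatments <- function(...) {
  list(
    "Raw"       = preprocess_spec(character(0), ...),
    "SG"        = preprocess_spec("sg", ...),
    "SNV"       = preprocess_spec("snv", ...),
    "DET"       = preprocess_spec("det", ...),
    "SG + SNV"  = preprocess_spec(c("sg", "snv"), ...),
    "SG + DET"  = preprocess_spec(c("sg", "det"), ...),
    "SNV + DET" = preprocess_spec(c("snv", "det"), ...)
  )
}

apply_step <- function(x, step, spec, grid) {
  switch(step,
    sg  = savgol(x, spec$sg_window, spec$sg_polyorder),
    snv = snv(x),
    det = detrend_spectrum(x, grid, spec$det_order),
    stop("unknown preprocessing step: ", step)
  )
}

#' Apply a preprocessing pipeline to a spectrum matrix
#'
#' Operators are applied row-wise (per spectrum) in the order listed in the
#' spec; the empty spec is the identity (Raw). Shape and metadata are
#' preserved. Per-row failures are reported with the row index.
#'
#' @param X a [spectrum_matrix()].
#' @param spec a [preprocess_spec()].
#' @return the preprocessed [spectrum_matrix()].
#' @export
preprocess <- function(X, spec = preprocess_spec()) {
  if (!inherits(X, "spectrum_matrix")) stop("`X` must be a spectrum_matrix")
  if (!inherits(spec, "preprocess_spec")) stop("`spec` must be a preprocess_spec")
  if (length(spec$steps) == 0) return(X)
  out <- X$values
  for (i in seq_len(nrow(out))) {
    row <- out[i, ]
    for (step in spec$steps) {
      row <- tryCatch(
        apply_step(row, step, spec, X$grid),
        error = function(e) stop(sprintf("row %d (%s): %s", i, step,
                                         conditionMessage(e)), call. = FALSE)
      )
    }
    out[i, ] <- row
  }
  spectrum_matrix(out, X$grid, sample_ids = X$sample_ids,
                  tissue = X$tissue, variety = X$variety)
}
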