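#' Hypercube container
#'
#' A 3-D array of intensities (lines x pixels x bands) with its wavelength
#' grid and a role flag. Raw cubes hold digital numbers; calibrated cubes
#' hold % transmittance.
#'
#' @param data 3-D numeric array, lines x pixels x bands.
#' @param grid a [wavelength_grid()] whose length matches `dim(data)[3]`.
#' @param kind one of `"raw"`, `"black"`, `"white"`, `"calibrated"`.
#' @return A `hypercube` object.
#' @export
hypercube <- function(data, grid, kind = c("raw", "black", "white", "calibrated")) {
  kind <- match.arg(kind)
  stopifnot_grid(grid)
  if (!is.array(data) || length(dim(data)) != 3) {
    stop("`data` must be a 3-D array (lines x pixels x bands)")
  }
  if (dim(data)[3] != length(grid)) {
    stop(sprintf("bands dimension (%d) does not match grid length (%d)",
                 dim(data)[3], length(grid)))
  }
  structure(list(data = data, grid = grid, kind = kind), class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube:%s> %d lines x %d pixels x %d bands\n",
              x$kind, d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Spectrum matrix container
#'
#' An n x p matrix of spectra (% transmittance) with wavelength grid,
#' sample IDs and tissue/variety metadata -- the tabular form downstream
#' preprocessing, selection and regression operate on.
#'
#' @param values numeric matrix, samples in rows, bands in columns.
#' @param grid a [wavelength_grid()], length `ncol(values)`.
#' @param sample_ids character vector, length `nrow(values)`.
#' @param tissue,variety free-text metadata labels.
#' @return A `spectrum_matrix` object.
#' @export
spectrum_matrix <- function(values, grid, sample_ids = NULL,
                            tissue = "unknown", variety = "unknown") {
  stopifnot_grid(grid)
  values <- as.matrix(values)
  if (nrow(values) < 1) stop("a spectrum matrix needs at least one row")
  if (ncol(values) != length(grid)) {
    stop(sprintf("spectrum length (%d) does not match grid length (%d)",
                 ncol(values), length(grid)))
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stop("spectrum matrix must be finite with no missing values")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(values)))
  if (length(sample_ids) != nrow(values)) stop("sample_ids length mismatch")
  rownames(values) <- sample_ids
  colnames(values) <- as.character(grid$labels)
  structure(
    list(values = values, grid = grid, sample_ids = sample_ids,
         tissue = tissue, variety = variety),
    class = "spectrum_matrix"
  )
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix> %d samples x %d bands (%s / %s)\n",
              nrow(x$values), ncol(x$values), x$tissue, x$variety))
  invisible(x)
}

#' @export
dim.spectrum_matrix <- function(x) dim(x$values)

#' Region-of-interest specification
#'
#' 0-based, half-open window `[top, top + height) x [left, left + width)`
#' in line/pixel coordinates. The default 100 x 100 window matches the
#' standard extraction protocol.
#'
#' @param top,left 0-based offsets of the top-left corner.
#' @param height,width window extents in pixels.
#' @return An `roi_spec` object.
#' @export
roi_spec <- function(top = 0L, left = 0L, height = 100L, width = 100L) {
  v <- as.integer(c(top, left, height, width))
  if (any(is.na(v)) || v[1] < 0 || v[2] < 0 || v[3] < 1 || v[4] < 1) {
    stop("ROI needs top/left >= 0 and height/width >= 1")
  }
  structure(list(top = v[1], left = v[2], height = v[3], width = v[4]),
            class = "roi_spec")
}

#' Black/white calibration of a raw hypercube
#'
#' Converts raw digital numbers to % transmittance per pixel and band:
#' `C = (R - B) / (W - B) * 100`, with `R` the raw cube, `B` the dark
#' frame and `W` the white reference. Degenerate positions where
#' `W <= B` (dead or saturated pixels) are set to `NA` and later excluded
#' from ROI means rather than aborting the run.
#'
#' @param raw,black,white [hypercube()] objects of identical shape and grid.
#' @return A calibrated [hypercube()] (values in %, `NA` where `W <= B`).
#' @examples
#' g <- wavelength_grid(5)
#' b <- hypercube(array(0,   c(2, 2, 5)), g, "black")
#' w <- hypercube(array(100, c(2, 2, 5)), g, "white")
#' r <- hypercube(array(50,  c(2, 2, 5)), g, "raw")
#' calibrate_cube(r, b, w)$data[1, 1, 1]  # 50
#' @export
calibrate_cube <- function(raw, black, white) {
  for (x in list(raw, black, white)) {
    if (!inherits(x, "hypercube")) stop("all three inputs must be hypercubes")
  }
  if (!identical(dim(raw$data), dim(black$data)) ||
      !identical(dim(raw$data), dim(white$data))) {
    stop("raw, black and white cubes must share the same shape")
  }
  if (raw$kind == "calibrated") stop("`raw` is already calibrated")
  denom <- white$data - black$data
  bad <- denom <= 0
  corrected <- (raw$data - black$data) / denom * 100
  if (any(bad)) {
    corrected[bad] <- NA_real_
    warning(sprintf("%d cube positions have white <= black; set to NA", sum(bad)))
  }
  hypercube(corrected, raw$grid, kind = "calibrated")
}

#' Mean ROI spectrum of a calibrated cube
#'
#' Per-band arithmetic mean over the ROI's pixels. `NA` positions left by
#' degenerate calibration are excluded; if more than `max_invalid_frac` of
#' the ROI pixels in any band are invalid the extraction is rejected.
#'
#' @param cube a calibrated [hypercube()].
#' @param roi an [roi_spec()]; must lie fully inside the cube.
#' @param max_invalid_frac tolerated fraction of invalid pixels per band.
#' @return numeric vector, one mean transmittance per band.
#' @export
extract_roi_mean <- function(cube, roi = roi_spec(), max_invalid_frac = 0.01) {
  if (!inherits(cube, "hypercube")) stop("`cube` must be a hypercube")
  if (cube$kind != "calibrated") stop("ROI extraction needs a calibrated cube")
  if (!inherits(roi, "roi_spec")) stop("`roi` must be an roi_spec")
  d <- dim(cube$data)
  if (roi$top + roi$height > d[1] || roi$left + roi$width > d[2]) {
    stop(sprintf(
      "ROI [top=%d, left=%d, %dx%d] exceeds cube extent %d x %d",
      roi$top, roi$left, roi$height, roi$width, d[1], d[2]
    ))
  }
  block <- cube$data[roi$top + seq_len(roi$height),
                     roi$left + seq_len(roi$width), , drop = FALSE]
  n_pix <- roi$height * roi$width
  invalid <- apply(is.na(block), 3, sum)
  if (any(invalid > max_invalid_frac * n_pix)) {
    stop(sprintf("band %d has %d/%d invalid ROI pixels (> %.1f%% tolerated)",
                 which.max(invalid), max(invalid), n_pix, 100 * max_invalid_frac))
  }
  apply(block, 3, mean, na.rm = TRUE)
}

#' Stack extracted spectra into a spectrum matrix
#'
#' @param spectra list of numeric vectors of equal length p (one per sample).
#' @param grid a [wavelength_grid()] of length p.
#' @param sample_ids optional IDs; defaults to list names or S0001...
#' @param tissue,variety metadata labels.
#' @return A [spectrum_matrix()] with rows in input order.
#' @export
stack_samples <- function(spectra, grid, sample_ids = NULL,
                          tissue = "unknown", variety = "unknown") {
  if (!is.list(spectra) || length(spectra) == 0) {
    stop("`spectra` must be a nonempty list of spectra")
  }
  lens <- lengths(spectra)
  if (length(unique(lens)) != 1) {
    stop("all spectra must share the same length; got lengths ",
         paste(unique(lens), collapse = ", "))
  }
  if (is.null(sample_ids) && !is.null(names(spectra))) sample_ids <- names(spectra)
  spectrum_matrix(do.call(rbind, spectra), grid, sample_ids = sample_ids,
                  tissue = tissue, variety = variety)
}
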