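#' Wavelength grid of an imaging spectrometer
#'
#' Builds the spectral axis shared by hypercubes and spectrum matrices.
#' The default grid reproduces the instrument geometry assumed throughout
#' the package: 616 bands uniformly spanning 365--1025 nm (about 1.07 nm
#' spacing). Band labels are the centers rounded to integer nanometres;
#' because the spacing is close to 1 nm, adjacent labels may repeat --
#' labels are display-only and all internal indexing is positional.
#'
#' @param n_bands number of spectral bands.
#' @param from,to first and last band center in nm.
#' @return An object of class `wavelength_grid`: a list with `band_centers`
#'   (strictly increasing numeric vector) and `labels` (integer nm).
#' @examples
#' g <- wavelength_grid()
#' length(g$band_centers)  # 616
#' range(g$band_centers)   # 365 1025
#' @export
wavelength_grid <- function(n_bands = 616L, from = 365, to = 1025) {
  n_bands <- as.integer(n_bands)
  if (n_bands < 2L) stop("a wavelength grid needs at least 2 bands")
  if (!(from < to)) stop("`from` must be below `to`")
  centers <- seq(from, to, length.out = n_bands)
  structure(
    list(band_centers = centers, labels = as.integer(round(centers))),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d bands, %.1f-%.1f nm (spacing %.3f nm)\n",
    length(x$band_centers), min(x$band_centers), max(x$band_centers),
    mean(diff(x$band_centers))
  ))
  invisible(x)
}

#' @export
length.wavelength_grid <- function(x) length(x$band_centers)

# internal: map wavelengths to [-1, 1] for polynomial conditioning
scale_unit <- function(lambda) {
  r <- range(lambda)
  if (diff(r) == 0) stop("degenerate wavelength axis")
  2 * (lambda - r[1]) / diff(r) - 1
}

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "wavelength_grid")) stop("`grid` must be a wavelength_grid")
  invisible(grid)
}
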