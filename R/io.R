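#' Write spectra and targets to CSV
#'
#' Layout: first column `sample_id`, one column per band labeled by its
#' rounded-nm wavelength (labels may repeat at ~1 nm band spacing; order is
#' positional), final column `anthocyanin_pct`.
#'
#' @param spectra a [spectrum_matrix()].
#' @param targets numeric target vector aligned to the rows (or `NULL`).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_spectra_csv <- function(spectra, targets, file) {
  if (!inherits(spectra, "spectrum_matrix")) stop("`spectra` must be a spectrum_matrix")
  n <- nrow(spectra$values)
  if (!is.null(targets) && length(targets) != n) {
    stop("targets length does not match spectra rows")
  }
  df <- data.frame(sample_id = spectra$sample_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(spectra$values, check.names = FALSE))
  if (!is.null(targets)) df$anthocyanin_pct <- targets
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read spectra and targets from CSV
#'
#' Inverse of [write_spectra_csv()]. Band columns are taken positionally
#' (everything between `sample_id` and `anthocyanin_pct`).
#'
#' @param file CSV path.
#' @param grid optional [wavelength_grid()]; if `NULL` a grid is rebuilt
#'   from the rounded column labels (integer nm, display precision only).
#' @param tissue,variety metadata labels for the rebuilt matrix.
#' @return list with `spectra` (a [spectrum_matrix()]) and `targets`
#'   (numeric or `NULL`).
#' @export
read_spectra_csv <- function(file, grid = NULL, tissue = "unknown", variety = "unknown") {
  df <- utils::read.csv(file, check.names = FALSE)
  if (names(df)[1] != "sample_id") stop("first CSV column must be sample_id")
  has_target <- names(df)[ncol(df)] == "anthocyanin_pct"
  band_cols <- 2:(ncol(df) - if (has_target) 1L else 0L)
  values <- as.matrix(df[, band_cols, drop = FALSE])
  if (is.null(grid)) {
    w <- as.numeric(names(df)[band_cols])
    if (anyNA(w)) stop("band column labels are not numeric wavelengths")
    grid <- structure(list(band_centers = w, labels = as.integer(round(w))),
                      class = "wavelength_grid")
  }
  list(
    spectra = spectrum_matrix(values, grid, sample_ids = as.character(df$sample_id),
                              tissue = tissue, variety = variety),
    targets = if (has_target) df$anthocyanin_pct else NULL
  )
}

#' Serialize a selection result to JSON
#'
#' @param result a `selection_result` from [cars_select()] or [spa_select()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_selection_json <- function(result, file) {
  if (!inherits(result, "selection_result")) stop("`result` must be a selection_result")
  obj <- list(
    method = result$method,
    selected = result$selected,
    selected_labels = result$selected_labels,
    best_iteration = result$best_iteration,
    trace = result$trace
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(file)
}

#' Write the selected bands as a rounded-nm label list
#'
#' One comma-separated line of integer-nm labels, the format of published
#' characteristic-band tables.
#'
#' @param result a `selection_result`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_band_list <- function(result, file) {
  if (!inherits(result, "selection_result")) stop("`result` must be a selection_result")
  writeLines(paste(result$selected_labels, collapse = ","), file)
  invisible(file)
}
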