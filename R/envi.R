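# ENVI raster I/O: text .hdr header + flat binary data block.
# Supported: interleave bsq/bil, byte order 0 (little-endian),
# data types 4 (float32), 5 (float64), 12 (uint16).

envi_type_size <- function(dtype) {
  switch(as.character(dtype), "4" = 4L, "5" = 8L, "12" = 2L,
         stop("unsupported ENVI data type: ", dtype))
}

#' Write a hypercube as an ENVI raster
#'
#' Writes the binary data block to `file` and the text header to
#' `<file>.hdr`. Band-sequential (BSQ) layout, little-endian. The header
#' carries the wavelength grid in its `wavelength` field.
#'
#' @param cube a [hypercube()].
#' @param file path of the binary data file; the header is `<file>.hdr`.
#' @param data_type ENVI data type code: 4 (float32, default), 5 (float64)
#'   or 12 (uint16).
#' @return `file`, invisibly.
#' @export
write_envi <- function(cube, file, data_type = 4L) {
  if (!inherits(cube, "hypercube")) stop("`cube` must be a hypercube")
  d <- dim(cube$data)
  size <- envi_type_size(data_type)
  hdr <- c(
    "ENVI",
    sprintf("description = {anthospec hypercube, kind = %s}", cube$kind),
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(format(cube$grid$band_centers, digits = 12, trim = TRUE,
                        scientific = FALSE), collapse = ", "),
           "}")
  )
  writeLines(hdr, paste0(file, ".hdr"))
  # BSQ: sample index fastest, then line, then band
  flat <- as.vector(aperm(cube$data, c(2, 1, 3)))
  con <- file(file, "wb")
  on.exit(close(con))
  if (data_type == 12L) {
    v <- as.integer(round(flat))
    if (any(v < 0 | v > 65535)) stop("values outside uint16 range for data type 12")
    v[v > 32767L] <- v[v > 32767L] - 65536L  # two's-complement wrap
    writeBin(v, con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(flat), con, size = size, endian = "little")
  }
  invisible(file)
}

parse_envi_header <- function(hdr_file) {
  txt <- paste(readLines(hdr_file, warn = FALSE), collapse = "\n")
  fields <- list()
  # values may be scalars or {...} blocks spanning lines
  pat <- "(?m)^\\s*([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("no fields found in ENVI header: ", hdr_file)
  for (i in seq_along(m)) {
    piece <- substr(txt, m[i], m[i] + attr(m, "match.length")[i] - 1)
    key <- tolower(trimws(sub("=.*", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    fields[[key]] <- val
  }
  fields
}

#' Read an ENVI raster into a hypercube
#'
#' @param file path of the binary data file; the header is looked up at
#'   `<file>.hdr` (falling back to replacing the extension with `.hdr`).
#' @param kind role flag for the returned cube.
#' @return A [hypercube()] with the wavelength grid taken from the header.
#' @export
read_envi <- function(file, kind = "raw") {
  hdr_file <- paste0(file, ".hdr")
  if (!file.exists(hdr_file)) hdr_file <- sub("\\.[^.]*$", ".hdr", file)
  if (!file.exists(hdr_file)) stop("ENVI header not found for ", file)
  h <- parse_envi_header(hdr_file)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  if (!all(need %in% names(h))) {
    stop("ENVI header missing fields: ",
         paste(setdiff(need, names(h)), collapse = ", "))
  }
  samples <- as.integer(h$samples); lines <- as.integer(h$lines)
  bands <- as.integer(h$bands); dtype <- as.integer(h[["data type"]])
  interleave <- tolower(h$interleave)
  byte_order <- if (!is.null(h[["byte order"]])) as.integer(h[["byte order"]]) else 0L
  if (byte_order != 0L) stop("only little-endian (byte order = 0) is supported")
  size <- envi_type_size(dtype)
  n <- samples * lines * bands
  con <- file(file, "rb")
  on.exit(close(con))
  flat <- if (dtype == 12L) {
    as.numeric(readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                       endian = "little"))
  } else {
    readBin(con, "numeric", n = n, size = size, endian = "little")
  }
  if (length(flat) != n) stop("ENVI data block shorter than header promises")
  data <- switch(interleave,
    bsq = aperm(array(flat, dim = c(samples, lines, bands)), c(2, 1, 3)),
    bil = aperm(array(flat, dim = c(samples, bands, lines)), c(3, 1, 2)),
    stop("unsupported interleave: ", interleave)
  )
  grid <- if (!is.null(h$wavelength)) {
    w <- as.numeric(strsplit(gsub("[{}]", "", h$wavelength), ",")[[1]])
    if (length(w) != bands) stop("wavelength list length does not match bands")
    structure(list(band_centers = w, labels = as.integer(round(w))),
              class = "wavelength_grid")
  } else {
    wavelength_grid(bands, 1, bands)
  }
  hypercube(data, grid, kind = kind)
}
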