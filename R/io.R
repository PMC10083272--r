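#' Read a hyperspectral cube from an ENVI header/binary pair
#'
#' Reads the band-interleaved-by-line (BIL) ENVI dialect written by
#' [write_cube()]: a text `.hdr` carrying dimensions, data type, interleave
#' and the `wavelength` block, next to a flat binary data file. Wavelengths
#' are required; cubes stored with descending wavelengths are re-sorted
#' ascending on load.
#'
#' @param path path to the `.hdr` file or to the data file (either works;
#'   the twin is found by swapping the extension).
#' @return A [spectral_cube()].
#' @export
read_cube <- function(path) {
  paths <- envi_pair(path)
  if (!file.exists(paths$hdr))
    stop("ENVI header not found: ", paths$hdr, call. = FALSE)
  if (!file.exists(paths$dat))
    stop("ENVI data file not found: ", paths$dat, call. = FALSE)
  hdr <- parse_envi_header(paths$hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ENVI header missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(hdr[["wavelength"]]))
    stop("ENVI header declares no wavelength vector", call. = FALSE)
  nsamp <- as.integer(hdr[["samples"]])   # columns
  nline <- as.integer(hdr[["lines"]])     # rows
  nband <- as.integer(hdr[["bands"]])
  wl <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1]])
  if (length(wl) != nband)
    stop("wavelength count does not match band count", call. = FALSE)
  dtype <- as.integer(hdr[["data type"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype, call. = FALSE))
  interleave <- tolower(hdr[["interleave"]])
  if (interleave != "bil")
    stop("only BIL interleave is supported, got ", interleave, call. = FALSE)
  n <- nsamp * nline * nband
  raw_vals <- readBin(paths$dat, what = "numeric", n = n + 1L, size = size,
                      endian = "little")
  if (length(raw_vals) != n)
    stop("ENVI data file is not rectangular: expected ", n, " values, got ",
         length(raw_vals), call. = FALSE)
  # BIL on disk: line-major, then band, then sample -> [sample, band, line]
  arr <- array(raw_vals, dim = c(nsamp, nband, nline))
  values <- aperm(arr, c(3L, 1L, 2L))  # (row, col, band)
  role <- hdr[["role"]] %||% "raw"
  meta <- list()
  if (!is.null(hdr[["description"]])) meta$description <- hdr[["description"]]
  spectral_cube(values, wl, role = role, meta = meta)
}

#' Write a hyperspectral cube as an ENVI header/binary pair
#'
#' Writes BIL interleave, little-endian. Reflectance cubes and references
#' are stored as 64-bit floats so round-trips are bit-exact.
#'
#' @param cube a [spectral_cube()].
#' @param path output path; `.hdr` and `.dat` extensions are derived from it.
#' @return The header path, invisibly usable with [read_cube()].
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  paths <- envi_pair(path)
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = { anthomap spectral cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bil",
    "byte order = 0",
    sprintf("role = %s", cube$role),
    sprintf("wavelength units = nm"),
    sprintf("band names = { %s }",
            paste(sprintf("Band %.4f nm", cube$wavelengths), collapse = ", ")),
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths, digits = 17), collapse = ", "))
  )
  ok <- tryCatch({
    writeLines(hdr, paths$hdr)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write ENVI header at ", paths$hdr, call. = FALSE)
  # (row, col, band) -> BIL disk order [sample, band, line]
  arr <- aperm(cube$values, c(2L, 3L, 1L))
  con <- file(paths$dat, "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 8L, endian = "little")
  invisible(paths$hdr)
}

envi_pair <- function(path) {
  base <- sub("\\.(hdr|dat)$", "", path)
  list(hdr = paste0(base, ".hdr"), dat = paste0(base, ".dat"))
}

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  # tokenize: key = value, where value may be a { } block spanning lines
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (!grepl("=", line, fixed = TRUE)) { i <- i + 1L; next }
    key <- tolower(trimws(sub("=.*$", "", line)))
    val <- trimws(sub("^[^=]*=", "", line))
    if (startsWith(val, "{")) {
      while (!grepl("\\}", val) && i < n) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
      val <- trimws(gsub("[{}]", "", val))
    }
    out[[key]] <- val
    i <- i + 1L
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spectral matrix to CSV
#'
#' Layout: first column `row_id`, then one column per wavelength named
#' `wl_<nm>`.
#'
#' @param m a [spectral_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(m, path) {
  stopifnot(inherits(m, "spectral_matrix"))
  df <- data.frame(row_id = m$row_ids, m$values, check.names = FALSE)
  names(df) <- c("row_id", sprintf("wl_%.6f", m$wavelengths))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectral matrix from CSV written by [write_spectra_csv()]
#'
#' @param path CSV path.
#' @return A [spectral_matrix()].
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "row_id" || !all(startsWith(names(df)[-1], "wl_")))
    stop("not a spectral matrix CSV (expected row_id, wl_* columns)",
         call. = FALSE)
  wl <- as.numeric(sub("^wl_", "", names(df)[-1]))
  spectral_matrix(as.matrix(df[, -1, drop = FALSE]), wl, row_ids = df$row_id)
}
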