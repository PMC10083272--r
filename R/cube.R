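#' Spectral cube
#'
#' A hyperspectral image held in memory as a `rows x cols x bands` array
#' with a strictly ascending wavelength vector (band centers, nm) and a
#' role tag describing what the cube is: a raw sensor image, a white
#' reference, a dark reference, or a calibrated reflectance image.
#'
#' Axis order is always `(row, col, band)` in memory regardless of the
#' on-disk interleave, so masks index cubes directly.
#'
#' @param values numeric array, `rows x cols x bands`.
#' @param wavelengths numeric vector of band centers in nm, one per band.
#'   If stored descending (or unsorted) the bands are re-sorted ascending
#'   and the array slices permuted consistently.
#' @param role one of `"raw"`, `"white"`, `"dark"`, `"reflectance"`.
#' @param meta optional named list of free-form acquisition metadata.
#'
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, wavelengths,
                          role = c("raw", "white", "dark", "reflectance"),
                          meta = list()) {
  role <- match.arg(role)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array (rows x cols x bands)", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3L])
    stop("length(wavelengths) must equal the band dimension", call. = FALSE)
  if (anyNA(wavelengths)) stop("wavelengths must be finite", call. = FALSE)
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    ord <- order(wavelengths)
    wavelengths <- wavelengths[ord]
    values <- values[, , ord, drop = FALSE]
    if (is.unsorted(wavelengths, strictly = TRUE))
      stop("wavelengths must be distinct", call. = FALSE)
  }
  if (role == "reflectance" && !all(is.finite(values)))
    stop("reflectance cube must contain only finite values", call. = FALSE)
  if (role == "dark" && any(values < 0))
    stop("dark cube must be non-negative", call. = FALSE)
  structure(
    list(values = values, wavelengths = wavelengths, role = role, meta = meta),
    class = "spectral_cube"
  )
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), role=%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$role))
  invisible(x)
}

#' Spectral matrix
#'
#' An `n x p` matrix of spectra (one row per sample or pixel) carrying its
#' wavelength vector and row identifiers. This is the working container
#' for mean ROI spectra and sampled pixel spectra.
#'
#' @param values numeric matrix, `n x p`, no missing values.
#' @param wavelengths numeric vector of length `p` (nm).
#' @param row_ids character vector of sample/pixel identifiers; defaults
#'   to `"r1"... "rn"`.
#' @return An object of class `spectral_matrix`.
#' @export
spectral_matrix <- function(values, wavelengths, row_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (ncol(values) != length(wavelengths))
    stop("ncol(values) must equal length(wavelengths)", call. = FALSE)
  if (anyNA(values)) stop("spectral_matrix must not contain missing values", call. = FALSE)
  if (is.null(row_ids)) row_ids <- paste0("r", seq_len(nrow(values)))
  if (length(row_ids) != nrow(values))
    stop("row_ids length must equal nrow(values)", call. = FALSE)
  dimnames(values) <- NULL
  structure(
    list(values = values, wavelengths = wavelengths, row_ids = as.character(row_ids)),
    class = "spectral_matrix"
  )
}

#' @export
dim.spectral_matrix <- function(x) dim(x$values)

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("<spectral_matrix> %d spectra x %d bands (%.1f-%.1f nm)\n",
              nrow(x$values), ncol(x$values),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Fruit mask
#'
#' Boolean pixel grid marking fruit tissue (the ROI) after background and,
#' optionally, stalk removal.
#'
#' @param grid logical matrix, `rows x cols`.
#' @return An object of class `fruit_mask` with fields `grid` and
#'   `n_fruit_pixels`.
#' @export
fruit_mask <- function(grid) {
  if (!is.matrix(grid) || !is.logical(grid))
    stop("`grid` must be a logical matrix", call. = FALSE)
  if (anyNA(grid)) stop("mask must not contain NA", call. = FALSE)
  structure(list(grid = grid, n_fruit_pixels = sum(grid)), class = "fruit_mask")
}

#' @export
print.fruit_mask <- function(x, ...) {
  cat(sprintf("<fruit_mask> %d x %d, %d fruit pixels\n",
              nrow(x$grid), ncol(x$grid), x$n_fruit_pixels))
  invisible(x)
}

#' Index of the band nearest a target wavelength
#'
#' Ties (a target exactly between two band centers) resolve toward the
#' lower wavelength.
#'
#' @param wavelengths ascending numeric vector (nm).
#' @param target target wavelength (nm).
#' @param tol optional maximum allowed |band - target| distance in nm;
#'   `Inf` disables the check.
#' @return integer band index.
#' @export
nearest_band <- function(wavelengths, target, tol = Inf) {
  d <- abs(wavelengths - target)
  i <- which(d == min(d))[1L]  # which() returns the first = lower wavelength
  if (d[i] > tol)
    stop(sprintf("no band within %g nm of %g nm", tol, target), call. = FALSE)
  i
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$wavelengths, b$wavelengths, tolerance = 1e-9))
}
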