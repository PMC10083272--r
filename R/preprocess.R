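#' Crop a spectral matrix to a wavelength window
#'
#' Keeps bands with `low <= wavelength <= high` (closed interval), order
#' preserved. The default window 450-1050 nm discards the noisy edge bands
#' of a visible/NIR instrument.
#'
#' @param m a [spectral_matrix()].
#' @param low,high window endpoints, nm.
#' @return A [spectral_matrix()] restricted to the window.
#' @export
crop_window <- function(m, low = 450, high = 1050) {
  stopifnot(inherits(m, "spectral_matrix"))
  keep <- m$wavelengths >= low & m$wavelengths <= high
  if (!any(keep))
    stop(sprintf("no bands inside [%g, %g] nm", low, high), call. = FALSE)
  spectral_matrix(m$values[, keep, drop = FALSE], m$wavelengths[keep],
                  row_ids = m$row_ids)
}

#' Standard normal variate transform
#'
#' Standardizes each spectrum (row) independently: subtract the row mean,
#' divide by the row standard deviation (sample, n-1 denominator by
#' default). Corrects multiplicative scatter and path-length effects, so
#' the output is invariant to per-row affine transforms `a*x + b`, a > 0.
#'
#' A row with (near-)zero spread cannot be standardized; it is returned as
#' zeros with a warning.
#'
#' @param m a [spectral_matrix()] with at least 2 bands.
#' @param population use the population (n) instead of sample (n-1)
#'   standard deviation.
#' @return A [spectral_matrix()] of standardized rows.
#' @export
snv <- function(m, population = FALSE) {
  stopifnot(inherits(m, "spectral_matrix"))
  x <- m$values
  p <- ncol(x)
  if (p < 2) stop("SNV needs at least 2 bands per spectrum", call. = FALSE)
  mu <- rowMeans(x)
  xc <- x - mu
  denom <- if (population) p else p - 1
  sdv <- sqrt(rowSums(xc^2) / denom)
  flat <- sdv < 1e-12
  if (any(flat)) {
    warning(sum(flat), " constant row(s) returned as zeros")
    sdv[flat] <- 1
    xc[flat, ] <- 0
  }
  spectral_matrix(xc / sdv, m$wavelengths, row_ids = m$row_ids)
}
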