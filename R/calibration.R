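#' Reflectance calibration against white and dark references
#'
#' Converts raw sensor counts to relative reflectance band by band:
#' `R = (I - D) / (W - D)`, where `I` is the raw image, `W` the white
#' reference and `D` the dark (shutter-closed) reference. This removes the
#' uneven light-source intensity distribution and the dark current.
#'
#' Cells where `W - D <= eps` carry no usable signal; they are set to 0
#' and counted in a warning. Output is clipped to `[0, 1.5]` (mild
#' super-unity reflectance from noise is tolerated, gross excursions are
#' not).
#'
#' @param raw,white,dark [spectral_cube()]s sharing shape and wavelengths.
#' @param eps guard threshold on the denominator.
#' @return A [spectral_cube()] with `role = "reflectance"`.
#' @export
calibrate <- function(raw, white, dark, eps = 1e-6) {
  stopifnot(inherits(raw, "spectral_cube"), inherits(white, "spectral_cube"),
            inherits(dark, "spectral_cube"))
  if (!same_geometry(raw, white) || !same_geometry(raw, dark))
    stop("raw, white and dark cubes must share shape and wavelengths",
         call. = FALSE)
  den <- white$values - dark$values
  bad <- den <= eps
  n_bad <- sum(bad)
  if (n_bad > 0) {
    warning(n_bad, " cell(s) with white - dark <= ", eps, " set to 0")
    den[bad] <- 1
  }
  r <- (raw$values - dark$values) / den
  r[bad] <- 0
  r[r < 0] <- 0
  r[r > 1.5] <- 1.5
  spectral_cube(r, raw$wavelengths, role = "reflectance", meta = raw$meta)
}

#' Segment fruit from background by NIR reflectance thresholding
#'
#' Fruit tissue is bright in the near infrared while the black cardboard
#' background is dark, so a pixel is marked fruit iff its reflectance at
#' the band nearest `seg_wavelength` is at least `threshold` (the
#' threshold is the minimum fruit reflectance).
#'
#' @param refl reflectance [spectral_cube()].
#' @param seg_wavelength segmentation wavelength, nm.
#' @param threshold minimum fruit reflectance at that band.
#' @return A [fruit_mask()]. An empty mask triggers a warning and is
#'   returned as-is.
#' @export
segment_fruit <- function(refl, seg_wavelength = 800, threshold = 0.2) {
  stopifnot(inherits(refl, "spectral_cube"))
  if (refl$role != "reflectance")
    stop("segment_fruit expects a reflectance cube", call. = FALSE)
  if (seg_wavelength < min(refl$wavelengths) ||
      seg_wavelength > max(refl$wavelengths))
    stop("seg_wavelength outside the cube's wavelength range", call. = FALSE)
  b <- nearest_band(refl$wavelengths, seg_wavelength)
  grid <- band_slice(refl, b) >= threshold
  m <- fruit_mask(grid)
  if (m$n_fruit_pixels == 0L)
    warning("segmentation produced an empty mask")
  m
}

#' Remove stalk pixels from a fruit mask by green-tissue contrast
#'
#' Chlorophyll-rich stalk tissue reflects more at 550 nm than at 670 nm
#' (where chlorophyll absorbs), while anthocyanin-rich flesh does not. A
#' masked pixel is retained iff `R(wl_a) - R(wl_b) <= max_diff` (signed
#' difference; set `absolute = TRUE` to use `|R(wl_a) - R(wl_b)|`).
#'
#' @param refl reflectance [spectral_cube()].
#' @param mask a [fruit_mask()] from [segment_fruit()] on the same cube.
#' @param wl_a,wl_b contrast wavelengths, nm.
#' @param max_diff maximum retained difference.
#' @param absolute compare the absolute difference instead of the signed one.
#' @return A [fruit_mask()], a subset of `mask`.
#' @export
remove_stalk <- function(refl, mask, wl_a = 550, wl_b = 670, max_diff = 0.04,
                         absolute = FALSE) {
  stopifnot(inherits(refl, "spectral_cube"), inherits(mask, "fruit_mask"))
  rng <- range(refl$wavelengths)
  if (wl_a < rng[1] || wl_a > rng[2] || wl_b < rng[1] || wl_b > rng[2])
    stop("contrast wavelengths outside the cube's range", call. = FALSE)
  ba <- nearest_band(refl$wavelengths, wl_a)
  bb <- nearest_band(refl$wavelengths, wl_b)
  d <- band_slice(refl, ba) - band_slice(refl, bb)
  if (absolute) d <- abs(d)
  fruit_mask(mask$grid & (d <= max_diff))
}

#' Mean ROI spectrum
#'
#' Arithmetic mean over the masked pixels, band by band.
#'
#' @param refl reflectance [spectral_cube()].
#' @param mask non-empty [fruit_mask()].
#' @param row_id identifier for the resulting single-row matrix.
#' @return A 1 x p [spectral_matrix()].
#' @export
mean_spectrum <- function(refl, mask, row_id = "roi_mean") {
  stopifnot(inherits(refl, "spectral_cube"), inherits(mask, "fruit_mask"))
  if (mask$n_fruit_pixels == 0L) stop("mask is empty", call. = FALSE)
  px <- pixel_matrix(refl, mask)
  spectral_matrix(matrix(colMeans(px), nrow = 1), refl$wavelengths,
                  row_ids = row_id)
}

#' Randomly sample pixel spectra from the ROI
#'
#' Draws `n` distinct masked pixels uniformly without replacement
#' (deterministic given `seed`). If the mask holds fewer than `n` pixels,
#' all of them are returned with a warning.
#'
#' @param refl reflectance [spectral_cube()].
#' @param mask [fruit_mask()].
#' @param n number of pixels to draw.
#' @param seed integer RNG seed.
#' @param id_prefix prefix for the row identifiers.
#' @return An n x p [spectral_matrix()].
#' @export
sample_pixels <- function(refl, mask, n = 400, seed = 1L, id_prefix = "px") {
  stopifnot(inherits(refl, "spectral_cube"), inherits(mask, "fruit_mask"))
  idx <- which(mask$grid)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  if (length(idx) < n) {
    warning("mask has only ", length(idx), " pixels; returning all of them")
    take <- idx
  } else {
    take <- with_seed(seed, sample(idx, n, replace = FALSE))
  }
  px <- pixel_matrix(refl, mask = NULL, idx = take)
  spectral_matrix(px, refl$wavelengths,
                  row_ids = paste0(id_prefix, "_", take))
}

# One band of a cube as a rows x cols matrix (drop-safe for 1-row cubes)
band_slice <- function(cube, b) {
  d <- dim(cube$values)
  matrix(cube$values[, , b], d[1], d[2])
}

# Extract masked pixels as an n x bands matrix (linear pixel index order)
pixel_matrix <- function(cube, mask = NULL, idx = NULL) {
  d <- dim(cube$values)
  flat <- matrix(cube$values, nrow = d[1] * d[2], ncol = d[3])
  if (is.null(idx)) idx <- which(mask$grid)
  flat[idx, , drop = FALSE]
}

# Run code under a local RNG seed without disturbing the global stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
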