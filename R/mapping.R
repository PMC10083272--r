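#' Bundle a trained model with its preprocessing chain
#'
#' Ties together everything needed to replay the training-time transform
#' on new spectra (mean ROI spectra or single pixels): the wavelength
#' window, the SNV step, the variable selector (band subset or SAE
#' encoder) and the regression model. Prediction order is fixed as
#' crop -> SNV -> select/encode -> model.
#'
#' @param model fitted regression model (`elm_model` or `lssvm_model`).
#' @param wavelengths the training wavelength vector after cropping.
#' @param window numeric `c(low, high)` crop window in nm.
#' @param selector `NULL` (all bands), a `selection_result` (band
#'   subset), or an `sae_model` (deep features).
#' @return List of class `model_bundle`.
#' @export
model_bundle <- function(model, wavelengths, window = c(450, 1050),
                         selector = NULL) {
  structure(list(model = model, wavelengths = as.numeric(wavelengths),
                 window = window, selector = selector),
            class = "model_bundle")
}

#' Apply a bundle's preprocessing chain to spectra
#'
#' @param bundle a [model_bundle()].
#' @param m a [spectral_matrix()] on the instrument grid.
#' @param tol maximum band-center mismatch tolerated after cropping, nm.
#' @return Feature matrix ready for the bundle's model.
#' @export
bundle_features <- function(bundle, m, tol = 2) {
  stopifnot(inherits(bundle, "model_bundle"), inherits(m, "spectral_matrix"))
  mc <- crop_window(m, bundle$window[1], bundle$window[2])
  if (length(mc$wavelengths) != length(bundle$wavelengths) ||
      max(abs(mc$wavelengths - bundle$wavelengths)) > tol)
    stop("cube wavelengths do not match the bundle's training grid",
         call. = FALSE)
  ms <- snv(mc)
  sel <- bundle$selector
  if (is.null(sel)) return(ms$values)
  if (inherits(sel, "sae_model")) return(sae_encode(sel, ms))
  if (inherits(sel, "selection_result"))
    return(ms$values[, sel$indices, drop = FALSE])
  stop("unknown selector type", call. = FALSE)
}

#' Predict a bundle on spectra
#'
#' @inheritParams bundle_features
#' @return Numeric vector of predicted contents (mg/g).
#' @export
predict_bundle <- function(bundle, m, tol = 2) {
  predict(bundle$model, bundle_features(bundle, m, tol = tol))
}

#' Per-pixel anthocyanin prediction map
#'
#' Runs every masked pixel's spectrum through the bundle's full chain
#' (crop -> per-pixel SNV -> band subset or SAE encoding -> model) and
#' assembles a map aligned with the mask. Unmasked pixels carry `NA`.
#' Execution is batched over pixels and is order- and batch-size
#' invariant (each pixel maps independently).
#'
#' @param refl reflectance [spectral_cube()].
#' @param mask [fruit_mask()] marking the ROI.
#' @param bundle a [model_bundle()].
#' @param smooth_sigma optional Gaussian smoothing of the assembled map
#'   (standard deviation in pixels, 0 = off). Per-pixel predictions
#'   carry independent sensor noise while pigment fields vary smoothly,
#'   so a narrow within-mask smoother suppresses noise with little
#'   signal loss. Smoothing is mask-aware: off-mask cells contribute
#'   nothing and stay `NA`.
#' @return List of class `prediction_map`: `values` (rows x cols, mg/g,
#'   `NA` off-mask), `mask`, `range` (finite value range).
#' @export
predict_map <- function(refl, mask, bundle, smooth_sigma = 0) {
  stopifnot(inherits(refl, "spectral_cube"), inherits(mask, "fruit_mask"))
  d <- dim(refl$values)
  if (!identical(dim(mask$grid), d[1:2]))
    stop("mask shape does not match the cube", call. = FALSE)
  vals <- matrix(NA_real_, d[1], d[2])
  idx <- which(mask$grid)
  if (length(idx)) {
    px <- spectral_matrix(pixel_matrix(refl, idx = idx), refl$wavelengths)
    vals[idx] <- predict_bundle(bundle, px)
    if (smooth_sigma > 0) vals <- masked_smooth(vals, mask$grid, smooth_sigma)
  }
  structure(list(values = vals, mask = mask,
                 range = if (length(idx)) range(vals[idx]) else c(NA, NA)),
            class = "prediction_map")
}

# normalized (mask-aware) separable Gaussian smoothing; NA outside mask
masked_smooth <- function(vals, mask, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm((-half):half, sd = sigma)
  conv_rows <- function(x) {
    t(apply(x, 1, function(v) {
      vp <- c(rep(0, half), v, rep(0, half))
      stats::convolve(vp, rev(k), type = "filter")
    }))
  }
  filled <- vals; filled[is.na(filled)] <- 0
  w <- matrix(as.numeric(mask), nrow(vals), ncol(vals))
  num <- conv_rows(t(conv_rows(t(filled))))
  den <- conv_rows(t(conv_rows(t(w))))
  out <- num / den
  out[!mask] <- NA_real_
  out
}

#' Render a prediction map as a pseudocolor PNG
#'
#' Masked pixels are colored by content along a monotone dark-to-warm
#' color ramp; the background is rendered neutral gray. A vertical
#' colorbar strip (low at the bottom, high at the top) is appended at the
#' right. Passing the same `scale` across scenes makes maps directly
#' comparable. Values outside `scale` are clipped in the rendering only,
#' never mutated in the data.
#'
#' @param pm a `prediction_map`.
#' @param out output PNG path.
#' @param scale numeric `c(min, max)` in mg/g; defaults to the map's own
#'   finite range.
#' @return `out`, invisibly.
#' @export
render_map <- function(pm, out, scale = NULL) {
  stopifnot(inherits(pm, "prediction_map"))
  if (is.null(scale)) scale <- pm$range
  stopifnot(scale[1] < scale[2])
  v <- pm$values
  u <- (v - scale[1]) / (scale[2] - scale[1])
  u[u < 0] <- 0; u[u > 1] <- 1
  rows <- nrow(v); cols <- ncol(v)
  img <- array(0.85, dim = c(rows, cols, 3))   # neutral background
  on_mask <- which(!is.na(u))
  if (length(on_mask)) {
    rgb_vals <- map_ramp(u[on_mask])
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[on_mask] <- rgb_vals[, ch]
      img[, , ch] <- plane
    }
  }
  # colorbar strip: 8 px wide, 2 px white separator
  bar_u <- seq(1, 0, length.out = rows)
  bar <- map_ramp(bar_u)
  strip <- array(1, dim = c(rows, 10, 3))
  for (ch in 1:3) strip[, 3:10, ch] <- matrix(bar[, ch], rows, 8)
  full <- array(0, dim = c(rows, cols + 10, 3))
  full[, seq_len(cols), ] <- img
  full[, cols + 1:10, ] <- strip
  ok <- tryCatch({ png::writePNG(full, out); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write PNG at ", out, call. = FALSE)
  invisible(out)
}

# monotone perceptual ramp (dark purple -> blue -> green -> yellow)
map_ramp <- function(u) {
  ramp <- grDevices::colorRamp(c("#440154", "#31688E", "#35B779", "#FDE725"),
                               space = "Lab")
  ramp(u) / 255
}

#' Compare a prediction map with the generator's ground truth
#'
#' Computed over the intersection of the map's mask and the truth fruit
#' mask: pixelwise determination coefficient, RMSE and mean signed error.
#'
#' @param pm a `prediction_map`.
#' @param truth a ground-truth list from [generate_scene()].
#' @return List: `r2`, `rmse`, `mean_error`, `n_pixels`.
#' @export
map_statistics <- function(pm, truth) {
  stopifnot(inherits(pm, "prediction_map"))
  if (!identical(dim(pm$values), dim(truth$concentration_map)))
    stop("map and truth shapes differ", call. = FALSE)
  inter <- pm$mask$grid & truth$fruit_mask$grid
  if (!any(inter)) stop("empty mask intersection", call. = FALSE)
  pred <- pm$values[inter]
  obs <- truth$concentration_map[inter]
  list(r2 = r_squared(obs, pred), rmse = rmse(obs, pred),
       mean_error = mean(pred - obs), n_pixels = sum(inter))
}
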