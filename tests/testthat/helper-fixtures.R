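# Small in-code fixtures shared across test files.

# tiny cube with known values: 2 x 2 pixels, 3 bands
tiny_cube <- function(role = "raw", wavelengths = c(500, 600, 700)) {
  vals <- array(seq_len(2 * 2 * 3) / 10, dim = c(2, 2, 3))
  spectral_cube(vals, wavelengths, role = role)
}

# uniform-valued cube (every pixel, band = value)
uniform_cube <- function(value, rows = 4, cols = 4,
                         wavelengths = c(500, 600, 700, 800),
                         role = "reflectance") {
  spectral_cube(array(value, c(rows, cols, length(wavelengths))),
                wavelengths, role = role)
}

# small, quick scene: 60 x 60 px, 2 fruits, reduced band grid
small_scene_spec <- function(seed = 1L, ...) {
  scene_spec(rows = 60, cols = 60, n_fruits = 2,
             wavelengths = seq(450, 1050, length.out = 80), seed = seed, ...)
}

# deterministic synthetic regression data: y depends on named columns
lin_data <- function(n, p, informative, beta, noise_sd, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, informative, drop = FALSE] %*% beta + rnorm(n, 0, noise_sd)
  list(X = X, y = as.numeric(y))
}

# flat view of selected pixels of a cube (independent re-implementation)
pixel_matrix_for_test <- function(cube, idx) {
  d <- dim(cube$values)
  matrix(cube$values, d[1] * d[2], d[3])[idx, , drop = FALSE]
}

# SNV-like pixel spectra with low intrinsic dimension for SAE tests:
# mixtures of two smooth archetype spectra plus noise, standardized
toy_pixel_spectra <- function(n = 400, p = 60, seed = 1) {
  set.seed(seed)
  wl <- seq(0, 1, length.out = p)
  s1 <- sin(2 * pi * wl); s2 <- exp(-(wl - 0.7)^2 / 0.02)
  a <- runif(n); b <- runif(n)
  X <- outer(a, s1) + outer(b, s2) + matrix(rnorm(n * p, 0, 0.02), n, p)
  t(apply(X, 1, function(r) (r - mean(r)) / sd(r)))
}
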