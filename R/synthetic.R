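#' Default synthetic wavelength grid
#'
#' 379 evenly spaced band centers spanning 450-1050 nm, matching the
#' variable count of the analysis window. `full = TRUE` instead returns a
#' grid over the instrument's nominal 305-1090 nm range at the same
#' spacing (used to exercise window cropping).
#'
#' @param full return the full-range grid.
#' @return Numeric vector of wavelengths (nm).
#' @export
default_wavelengths <- function(full = FALSE) {
  if (full) seq(305, 1090, by = 600 / 378) else seq(450, 1050, length.out = 379)
}

#' Parametric fruit reflectance model
#'
#' Baseline visible/NIR reflectance minus Gaussian absorption terms:
#' a broad anthocyanin band centered at 535 nm (spanning roughly
#' 500-700 nm) whose depth saturates with concentration, a chlorophyll
#' band at 680 nm, and water/sugar bands at 840 and 970 nm. A fourth,
#' optional absorber-free green-reflectance term at 550 nm models
#' chlorophyll-rich stalk tissue. The result is clipped to [0.01, 0.99]
#' and is strictly decreasing in `c_anth` wherever the anthocyanin band
#' has weight (e.g. 600 nm).
#'
#' @param wavelength wavelength(s), nm (vectorized).
#' @param c_anth anthocyanin concentration, mg/g (clamped at 0).
#' @param c_chl chlorophyll level, relative units (decreases with maturity).
#' @param c_water water/sugar level, relative units.
#' @param c_green green-tissue reflectance bump, relative units (stalks).
#' @return Reflectance in [0.01, 0.99].
#' @export
reflectance_model <- function(wavelength, c_anth, c_chl = 0, c_water = 0,
                              c_green = 0) {
  c_anth <- pmax(c_anth, 0); c_chl <- pmax(c_chl, 0)
  c_water <- pmax(c_water, 0); c_green <- pmax(c_green, 0)
  base <- 0.30 + 0.38 / (1 + exp(-(wavelength - 700) / 80))
  g <- function(center, width) exp(-(wavelength - center)^2 / (2 * width^2))
  depth_anth <- 0.55 * c_anth / (c_anth + 1.5)   # saturating Beer-like depth
  r <- base -
    depth_anth * g(535, 70) -
    0.25 * c_chl * g(680, 12) -
    c_water * (0.08 * g(840, 20) + 0.12 * g(970, 25)) +
    c_green * 0.05 * g(550, 35)
  pmin(pmax(r, 0.01), 0.99)
}

#' Scene specification
#'
#' Describes one synthetic sample: a tray of `n_fruits` fruits of one
#' variety at one maturity stage imaged on black cardboard.
#'
#' @param variety `"A"` or `"B"` (A is the darker, higher-anthocyanin one).
#' @param stage maturity stage `"S1"` (red), `"S2"` (red-to-purple) or
#'   `"S3"` (full).
#' @param anthocyanin_mean sample mean anthocyanin content, mg/g.
#' @param anthocyanin_cv within-fruit coefficient of variation of the
#'   lognormal concentration field. The default is stage-dependent
#'   (S1 0.20, S2 0.15, S3 0.10): pigment distribution is most uneven at
#'   red maturity and homogenizes as the fruit fully ripens.
#' @param c_chl chlorophyll level of the flesh (stage-dependent).
#' @param c_water water/sugar band level.
#' @param n_fruits fruits per sample.
#' @param rows,cols image size in pixels.
#' @param wavelengths band centers, nm.
#' @param noise_sd sensor noise standard deviation of the raw image, in
#'   reflectance units.
#' @param white_noise_sd,dark_noise_sd noise on the white and dark
#'   reference scans (reference panels are brighter and usually
#'   averaged, so their noise is lower than the raw scan's).
#' @param seed integer seed; scenes are deterministic given the spec.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(variety = "A", stage = "S2", anthocyanin_mean = 2,
                       anthocyanin_cv = NULL, c_chl = NULL, c_water = 0.8,
                       n_fruits = 6, rows = 120, cols = 120,
                       wavelengths = default_wavelengths(),
                       noise_sd = 0.005, white_noise_sd = 0.002,
                       dark_noise_sd = 0.001, seed = 1L) {
  stopifnot(variety %in% c("A", "B"), stage %in% c("S1", "S2", "S3"),
            anthocyanin_mean >= 0, n_fruits >= 1)
  if (is.null(anthocyanin_cv))
    anthocyanin_cv <- c(S1 = 0.20, S2 = 0.15, S3 = 0.10)[[stage]]
  stopifnot(anthocyanin_cv >= 0)
  if (is.null(c_chl))
    c_chl <- c(S1 = 0.8, S2 = 0.4, S3 = 0.15)[[stage]]
  structure(list(variety = variety, stage = stage,
                 anthocyanin_mean = anthocyanin_mean,
                 anthocyanin_cv = anthocyanin_cv, c_chl = c_chl,
                 c_water = c_water, n_fruits = n_fruits, rows = rows,
                 cols = cols, wavelengths = as.numeric(wavelengths),
                 noise_sd = noise_sd, white_noise_sd = white_noise_sd,
                 dark_noise_sd = dark_noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

# Separable Gaussian blur with replicate padding (small helper for the
# within-fruit concentration field)
gauss_blur <- function(x, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    stats::convolve(vp, rev(k), type = "filter")
  }
  x <- apply(x, 2, pad_conv)
  t(apply(t(x), 2, pad_conv))
}

#' Generate one synthetic scene (raw/white/dark cube triplet + ground truth)
#'
#' Fruits are ellipses with a smooth lognormal within-fruit anthocyanin
#' field (Gaussian-filtered white noise, exponentiated, rescaled so the
#' fruit-mask mean equals `anthocyanin_mean` exactly); each fruit carries
#' a short green stalk. The background is dark cardboard (R(800) < 0.1).
#' Acquisition is emulated as
#' `white = dark_level + gain(lambda) * illumination + noise`,
#' `raw = dark_level + gain(lambda) * illumination * R_true + noise`,
#' with a separable quadratic illumination gradient (about +/-10%) and a
#' small positive dark current, so that white/dark calibration recovers
#' the injected reflectance field up to noise.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements `raw`, `white`, `dark` (cubes) and `truth`
#'   (list: `concentration_map`, `fruit_mask`, `stalk_mask`,
#'   `sample_mean_content`, `c_chl`, `c_water`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  rows <- spec$rows; cols <- spec$cols; wl <- spec$wavelengths
  nb <- length(wl)

  ## --- geometry: ellipses on a jittered grid, stalk patch above each ---
  nf <- spec$n_fruits
  grid_c <- ceiling(sqrt(nf)); grid_r <- ceiling(nf / grid_c)
  cell_h <- rows / grid_r; cell_w <- cols / grid_c
  a <- 0.30 * cell_h; b <- 0.33 * cell_w   # semi-axes
  if (a < 3 || b < 3)
    stop("image too small to place ", nf, " fruits", call. = FALSE)
  fruit <- matrix(FALSE, rows, cols)
  stalk <- matrix(FALSE, rows, cols)
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  k <- 0L
  for (gi in seq_len(grid_r)) for (gj in seq_len(grid_c)) {
    if (k >= nf) break
    k <- k + 1L
    cy <- (gi - 0.5) * cell_h + stats::runif(1, -0.05, 0.05) * cell_h
    cx <- (gj - 0.5) * cell_w + stats::runif(1, -0.05, 0.05) * cell_w
    ai <- a * stats::runif(1, 0.85, 1.0); bi <- b * stats::runif(1, 0.85, 1.0)
    el <- ((rr - cy) / ai)^2 + ((cc - cx) / bi)^2 <= 1
    fruit <- fruit | el
    # stalk: thin vertical patch from the fruit top edge upward
    sr <- round(cy - ai); sl <- max(1, round(sr - 0.35 * ai))
    scol <- round(cx) + (-1:1)
    srow <- sl:max(sl, sr)
    srow <- srow[srow >= 1 & srow <= rows]
    scol <- scol[scol >= 1 & scol <= cols]
    if (length(srow) && length(scol)) stalk[srow, scol] <- TRUE
  }
  stalk <- stalk & !fruit

  ## --- within-fruit lognormal concentration field ---
  cvw <- spec$anthocyanin_cv
  conc <- matrix(0, rows, cols)
  if (any(fruit)) {
    if (cvw > 0) {
      sig <- sqrt(log(1 + cvw^2))
      z <- matrix(stats::rnorm(rows * cols), rows, cols)
      z <- gauss_blur(z, sigma = 3)
      z <- z / stats::sd(z)               # unit-variance smooth field
      field <- exp(sig * z - sig^2 / 2)
    } else field <- matrix(1, rows, cols)
    conc[fruit] <- spec$anthocyanin_mean * field[fruit]
    mu <- mean(conc[fruit])
    if (mu > 0) conc[fruit] <- conc[fruit] * spec$anthocyanin_mean / mu
  }

  ## --- per-pixel true reflectance, built per tissue class ---
  # flesh: anthocyanin + stage chlorophyll + water bands
  # stalk: chlorophyll-rich green tissue; background: dark cardboard
  bg_shape <- 0.04 + 0.02 * (wl - 450) / 600     # dark cardboard, R(800) < 0.1
  refl <- matrix(rep(bg_shape, each = rows * cols), rows * cols, nb)
  fidx <- which(fruit)
  if (length(fidx)) {
    depth <- 0.55 * conc[fidx] / (conc[fidx] + 1.5)
    base <- 0.30 + 0.38 / (1 + exp(-(wl - 700) / 80))
    g535 <- exp(-(wl - 535)^2 / (2 * 70^2))
    g680 <- exp(-(wl - 680)^2 / (2 * 12^2))
    gwat <- 0.08 * exp(-(wl - 840)^2 / (2 * 20^2)) +
            0.12 * exp(-(wl - 970)^2 / (2 * 25^2))
    flesh <- matrix(rep(base - spec$c_chl * 0.25 * g680 - spec$c_water * gwat,
                        each = length(fidx)), length(fidx), nb)
    flesh <- flesh - outer(depth, g535)
    refl[fidx, ] <- pmin(pmax(flesh, 0.01), 0.99)
  }
  sidx <- which(stalk)
  if (length(sidx)) {
    st <- reflectance_model(wl, c_anth = 0, c_chl = 0.8,
                            c_water = 0.3 * spec$c_water, c_green = 1)
    refl[sidx, ] <- matrix(rep(st, each = length(sidx)), length(sidx), nb)
  }

  ## --- acquisition: illumination gradient, gain, dark current, noise ---
  u <- (2 * seq_len(rows) / (rows + 1) - 1)      # -1..1
  v <- (2 * seq_len(cols) / (cols + 1) - 1)
  illum <- outer(1 - 0.1 * u^2, 1 - 0.1 * v^2)   # separable quadratic, ~±10%
  gain <- 4000 * (0.6 + 0.4 * exp(-((wl - 720) / 250)^2))
  dark_level <- 0.03 * gain

  npx <- rows * cols
  il <- as.vector(illum)
  w_sd <- spec$white_noise_sd %||% 0.002
  d_sd <- spec$dark_noise_sd %||% 0.001
  raw_v <- matrix(0, npx, nb)
  white_v <- matrix(0, npx, nb)
  dark_v <- matrix(0, npx, nb)
  for (bi in seq_len(nb)) {   # per band: keeps allocations small
    gb <- gain[bi]; db <- dark_level[bi]
    raw_v[, bi] <- pmax(db + gb * (il * refl[, bi] +
                                     spec$noise_sd * stats::rnorm(npx)), 0)
    white_v[, bi] <- db + gb * (il + w_sd * stats::rnorm(npx))
    dark_v[, bi] <- pmax(db + gb * d_sd * stats::rnorm(npx), 0)
  }

  meta <- list(variety = spec$variety, stage = spec$stage, seed = spec$seed)
  # (npx x nb) and (rows x cols x nb) share one memory layout: re-dim in place
  dim(raw_v) <- c(rows, cols, nb)
  dim(white_v) <- c(rows, cols, nb)
  dim(dark_v) <- c(rows, cols, nb)
  list(
    raw   = spectral_cube(raw_v,   wl, "raw",   meta),
    white = spectral_cube(white_v, wl, "white", meta),
    dark  = spectral_cube(dark_v,  wl, "dark",  meta),
    truth = list(
      concentration_map = conc,
      fruit_mask = fruit_mask(fruit),
      stalk_mask = stalk,
      sample_mean_content = if (any(fruit)) mean(conc[fruit]) else 0,
      c_chl = spec$c_chl, c_water = spec$c_water
    )
  )
}

#' Generate the two-variety, three-stage study design
#'
#' Emits a design table of `2 * n_per_variety` scene specifications (equal
#' thirds per maturity stage) plus the matching wet-chemistry reference
#' table. Stage mean contents increase with maturity and variety A exceeds
#' variety B at equal stage; individual samples scatter around their stage
#' mean with a lognormal between-sample CV. Reference absorbance
#' quadruples are back-computed from each scene's true mean content via
#' the inverse pH-differential relation plus measurement noise on the
#' differential absorbance.
#'
#' Scene cubes are not materialized here (180 scenes would not fit in
#' memory at once); each design row carries a derived seed so
#' [generate_scene()] reproduces its cubes on demand, bit-identically.
#'
#' @param n_per_variety samples per variety; must be divisible by 3.
#' @param seed master seed; per-scene seeds are derived from it.
#' @param stage_means named list with numeric `A` and `B` vectors of
#'   per-stage mean contents (mg/g), ascending S1..S3.
#' @param between_cv between-sample lognormal CV around the stage mean.
#' @param noise_sd_absorbance measurement noise sd on the differential
#'   absorbance (0 disables it).
#' @param constants a [chem_constants()] object.
#' @param ... further arguments passed to every [scene_spec()]
#'   (e.g. `rows`, `cols`, `wavelengths`, `noise_sd`).
#' @return A list with `design` (data.frame of scene parameters incl.
#'   per-scene `seed`), `reference` (data.frame: sample_id, variety,
#'   stage, absorbance quadruple, mass_g, content_mg_g, true_content) and
#'   `scene_specs` (list of [scene_spec()]s, same order).
#' @export
generate_study <- function(n_per_variety = 90, seed = 1L,
                           stage_means = list(A = c(1.0, 2.5, 4.5),
                                              B = c(0.7, 1.9, 3.6)),
                           between_cv = 0.15,
                           noise_sd_absorbance = 0.005,
                           constants = chem_constants(), ...) {
  if (n_per_variety %% 3 != 0)
    stop("n_per_variety must be divisible by 3 (equal stages)", call. = FALSE)
  n_stage <- n_per_variety / 3
  varieties <- c("A", "B"); stages <- c("S1", "S2", "S3")
  design <- expand.grid(rep = seq_len(n_stage), stage = stages,
                        variety = varieties, stringsAsFactors = FALSE)
  n <- nrow(design)
  design$sample_id <- sprintf("%s_%s_%02d", design$variety, design$stage,
                              design$rep)
  design <- design[, c("sample_id", "variety", "stage", "rep")]

  res <- with_seed(seed, {
    sig <- sqrt(log(1 + between_cv^2))
    sm <- mapply(function(v, s) stage_means[[v]][match(s, stages)],
                 design$variety, design$stage)
    mean_content <- sm * exp(stats::rnorm(n, -sig^2 / 2, sig))
    scene_seed <- sample.int(2^31 - 2, n)
    a_noise <- if (noise_sd_absorbance > 0)
      stats::rnorm(n, 0, noise_sd_absorbance) else numeric(n)
    # plausible baseline readings for the non-informative channels
    a700_ph1 <- stats::runif(n, 0.02, 0.06)
    a520_ph45 <- stats::runif(n, 0.08, 0.14)
    a700_ph45 <- stats::runif(n, 0.02, 0.05)
    mass <- stats::rnorm(n, constants$M, 0.001)
    list(mean_content = mean_content, scene_seed = scene_seed,
         a_noise = a_noise, a700_ph1 = a700_ph1, a520_ph45 = a520_ph45,
         a700_ph45 = a700_ph45, mass = mass)
  })

  design$anthocyanin_mean <- res$mean_content
  design$seed <- res$scene_seed

  specs <- lapply(seq_len(n), function(i)
    scene_spec(variety = design$variety[i], stage = design$stage[i],
               anthocyanin_mean = design$anthocyanin_mean[i],
               seed = design$seed[i], ...))

  # wet chemistry: true content -> differential absorbance (+ noise) ->
  # absorbance quadruple; content column recomputed through the forward path
  A_true <- absorbance_for_content(res$mean_content,
                                   replace_mass(constants, res$mass))
  A_meas <- A_true + res$a_noise
  a520_ph1 <- A_meas + res$a700_ph1 + (res$a520_ph45 - res$a700_ph45)
  content <- anthocyanin_content(
    differential_absorbance(a520_ph1, res$a700_ph1, res$a520_ph45,
                            res$a700_ph45),
    replace_mass(constants, res$mass))
  reference <- data.frame(
    sample_id = design$sample_id, variety = design$variety,
    stage = design$stage,
    a520_ph1 = a520_ph1, a700_ph1 = res$a700_ph1,
    a520_ph45 = res$a520_ph45, a700_ph45 = res$a700_ph45,
    mass_g = res$mass, content_mg_g = content,
    true_content = res$mean_content,
    stringsAsFactors = FALSE
  )
  list(design = design, reference = reference, scene_specs = specs)
}

replace_mass <- function(constants, mass) {
  # vectorized-mass variant of the constants (content is per-sample)
  structure(list(MW = constants$MW, DF = constants$DF, V = constants$V,
                 epsilon = constants$epsilon,
                 path_length = constants$path_length, M = mass),
            class = "chem_constants")
}
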