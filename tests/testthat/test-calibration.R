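make_triplet <- function(I, W, D, wl = c(500, 600, 700)) {
  shp <- c(2, 2, length(wl))
  list(raw = spectral_cube(array(I, shp), wl, "raw"),
       white = spectral_cube(array(W, shp), wl, "white"),
       dark = spectral_cube(array(D, shp), wl, "dark"))
}

test_that("calibration identities: I=D gives 0, I=W gives 1, hand value 0.5", {
  eq <- make_triplet(5, 105, 5)
  r0 <- calibrate(eq$dark, eq$white, eq$dark)   # I == D everywhere
  expect_true(all(r0$values == 0))
  r1 <- calibrate(eq$white, eq$white, eq$dark)  # I == W everywhere
  expect_true(all(r1$values == 1))
  rh <- calibrate(make_triplet(55, 105, 5)$raw, eq$white, eq$dark)
  expect_true(all(abs(rh$values - 0.5) < 1e-12))
})

test_that("calibration is invariant to affine re-scaling of the counts", {
  set.seed(11)
  wl <- c(500, 600, 700)
  shp <- c(3, 3, 3)
  D <- array(runif(27, 1, 2), shp)
  W <- D + array(runif(27, 5, 10), shp)
  I <- D + (W - D) * array(runif(27, 0.1, 0.9), shp)  # R in (0,1): no clipping
  a <- 3.7; b <- 11
  r1 <- calibrate(spectral_cube(I, wl, "raw"), spectral_cube(W, wl, "white"),
                  spectral_cube(D, wl, "dark"))
  r2 <- calibrate(spectral_cube(a * I + b, wl, "raw"),
                  spectral_cube(a * W + b, wl, "white"),
                  spectral_cube(a * D + b, wl, "dark"))
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
})

test_that("degenerate denominator cells are zeroed with a warning; shape mismatch errors", {
  t1 <- make_triplet(5, 105, 5)
  expect_warning(r <- calibrate(t1$raw, t1$dark, t1$dark), "set to 0")
  expect_true(all(r$values == 0))
  small <- spectral_cube(array(1, c(1, 2, 3)), c(500, 600, 700), "white")
  expect_error(calibrate(t1$raw, small, t1$dark), "share shape")
})

test_that("fruit segmentation thresholds at the band nearest 800 nm", {
  wl <- c(500, 600, 700, 800)
  vals <- array(0.05, c(2, 2, 4))
  vals[1, 1, 4] <- 0.6; vals[2, 2, 4] <- 0.2   # exactly at threshold: fruit
  refl <- spectral_cube(vals, wl, "reflectance")
  m <- segment_fruit(refl)
  expect_true(m$grid[1, 1]); expect_true(m$grid[2, 2])
  expect_false(m$grid[1, 2]); expect_false(m$grid[2, 1])
  expect_equal(m$n_fruit_pixels, 2L)
})

test_that("uniform background gives an empty mask with warning; threshold 0 marks all", {
  refl <- uniform_cube(0.05)
  expect_warning(m <- segment_fruit(refl), "empty")
  expect_equal(m$n_fruit_pixels, 0L)
  m_all <- segment_fruit(refl, threshold = 0)
  expect_equal(m_all$n_fruit_pixels, prod(dim(refl$values)[1:2]))
})

test_that("stalk removal applies the signed 550/670 difference rule", {
  wl <- c(550, 670, 800)
  vals <- array(0.5, c(1, 3, 3))       # all pass the 800 nm gate
  vals[1, 1, 1] <- 0.30; vals[1, 1, 2] <- 0.20  # diff 0.10 -> removed
  vals[1, 2, 1] <- 0.25; vals[1, 2, 2] <- 0.25  # diff 0    -> retained
  vals[1, 3, 1] <- 0.10; vals[1, 3, 2] <- 0.30  # diff -0.2 -> retained
  refl <- spectral_cube(vals, wl, "reflectance")
  mask <- segment_fruit(refl)
  kept <- remove_stalk(refl, mask)
  expect_equal(as.vector(kept$grid), c(FALSE, TRUE, TRUE))
  # absolute-difference variant also drops the third pixel
  kept_abs <- remove_stalk(refl, mask, absolute = TRUE)
  expect_equal(as.vector(kept_abs$grid), c(FALSE, TRUE, FALSE))
  # output is always a subset of the input mask
  expect_true(all(!kept$grid | mask$grid))
})

test_that("mean spectrum: single pixel, two-pixel average, permutation invariance", {
  wl <- c(500, 600, 700)
  vals <- array(0, c(2, 1, 3))
  s <- c(0.2, 0.4, 0.6); t <- c(0.8, 0.6, 0.4)
  vals[1, 1, ] <- s; vals[2, 1, ] <- t
  refl <- spectral_cube(vals, wl, "reflectance")
  one <- fruit_mask(matrix(c(TRUE, FALSE), 2, 1))
  expect_equal(as.vector(mean_spectrum(refl, one)$values), s)
  both <- fruit_mask(matrix(TRUE, 2, 1))
  expect_equal(as.vector(mean_spectrum(refl, both)$values), (s + t) / 2)
  empty <- fruit_mask(matrix(FALSE, 2, 1))
  expect_error(mean_spectrum(refl, empty), "empty")
})

test_that("pixel sampling is deterministic by seed, distinct across seeds", {
  refl <- uniform_cube(0.5, rows = 20, cols = 20)
  mask <- fruit_mask(matrix(TRUE, 20, 20))
  a <- sample_pixels(refl, mask, n = 50, seed = 3)
  b <- sample_pixels(refl, mask, n = 50, seed = 3)
  c <- sample_pixels(refl, mask, n = 50, seed = 4)
  expect_identical(a$row_ids, b$row_ids)
  expect_false(identical(a$row_ids, c$row_ids))
  expect_equal(nrow(a$values), 50)
  expect_equal(anyDuplicated(a$row_ids), 0L)
})

test_that("sampling a mask smaller than n returns all pixels with a warning", {
  refl <- uniform_cube(0.5, rows = 3, cols = 3)
  g <- matrix(FALSE, 3, 3); g[1, 1] <- TRUE; g[2, 2] <- TRUE
  mask <- fruit_mask(g)
  expect_warning(px <- sample_pixels(refl, mask, n = 10, seed = 1), "only")
  expect_equal(nrow(px$values), 2)
  one <- fruit_mask(matrix(c(TRUE, rep(FALSE, 8)), 3, 3))
  expect_silent(p1 <- sample_pixels(refl, one, n = 1, seed = 1))
  expect_equal(nrow(p1$values), 1)
})
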