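test_that("reflectance model: zero absorbers give the smooth baseline", {
  wl <- seq(450, 1050, by = 10)
  r <- reflectance_model(wl, 0, 0, 0)
  base <- 0.30 + 0.38 / (1 + exp(-(wl - 700) / 80))
  expect_equal(r, pmin(pmax(base, 0.01), 0.99))
})

test_that("reflectance at 600 nm strictly decreases with anthocyanin", {
  r <- reflectance_model(600, c(0, 0.5, 1, 2, 5, 10), c_chl = 0.3,
                         c_water = 0.8)
  expect_true(all(diff(r) < 0))
  expect_lt(reflectance_model(600, 5, 0.3, 0.8),
            reflectance_model(600, 1, 0.3, 0.8))
})

test_that("chlorophyll puts the local minimum within 680 +/- 5 nm", {
  wl <- seq(660, 700, by = 0.5)
  r <- reflectance_model(wl, c_anth = 0.5, c_chl = 0.8, c_water = 0)
  expect_lt(abs(wl[which.min(r)] - 680), 5)
})

test_that("water/sugar bands produce absorption dips near 840 and 970 nm", {
  wl <- seq(800, 1010, by = 1)
  r <- reflectance_model(wl, 0, 0, c_water = 1)
  r0 <- reflectance_model(wl, 0, 0, c_water = 0)
  dip <- r0 - r
  expect_lt(abs(wl[which.max(dip * (wl < 900))] - 840), 10)
  expect_lt(abs(wl[which.max(dip * (wl >= 900))] - 970), 10)
})

test_that("scene generation is deterministic given the seed", {
  a <- generate_scene(small_scene_spec(seed = 9))
  b <- generate_scene(small_scene_spec(seed = 9))
  expect_identical(a$raw$values, b$raw$values)
  expect_identical(a$white$values, b$white$values)
  expect_identical(a$dark$values, b$dark$values)
  expect_identical(a$truth$concentration_map, b$truth$concentration_map)
  c <- generate_scene(small_scene_spec(seed = 10))
  expect_false(identical(a$raw$values, c$raw$values))
})

test_that("scene ground truth satisfies its own invariants", {
  sc <- generate_scene(small_scene_spec(seed = 2, anthocyanin_mean = 2))
  tr <- sc$truth
  expect_equal(mean(tr$concentration_map[tr$fruit_mask$grid]),
               tr$sample_mean_content, tolerance = 1e-9)
  expect_equal(tr$sample_mean_content, 2)
  # stalk and fruit masks are disjoint; concentration is 0 off-fruit
  expect_false(any(tr$stalk_mask & tr$fruit_mask$grid))
  expect_true(all(tr$concentration_map[!tr$fruit_mask$grid] == 0))
})

test_that("calibrating the generated triplet recovers the injected reflectance", {
  spec <- small_scene_spec(seed = 4, anthocyanin_mean = 1.5)
  sc <- generate_scene(spec)
  refl <- calibrate(sc$raw, sc$white, sc$dark)
  idx <- which(sc$truth$fruit_mask$grid)
  measured <- colMeans(pixel_matrix_for_test(refl, idx))
  conc <- sc$truth$concentration_map[idx]
  modeled <- rowMeans(vapply(conc, function(cc)
    reflectance_model(spec$wavelengths, cc, spec$c_chl, spec$c_water),
    numeric(length(spec$wavelengths))))
  expect_lt(max(abs(measured - modeled)), 0.02)
})

test_that("background is dark at 800 nm and the stalk contrast is discriminative", {
  spec <- small_scene_spec(seed = 5)
  sc <- generate_scene(spec)
  refl <- calibrate(sc$raw, sc$white, sc$dark)
  b800 <- nearest_band(refl$wavelengths, 800)
  bg <- !(sc$truth$fruit_mask$grid | sc$truth$stalk_mask)
  expect_lt(mean(refl$values[, , b800][bg]), 0.1)
  # stalk pixels: R(550) - R(670) well above the 0.04 threshold
  b550 <- nearest_band(refl$wavelengths, 550)
  b670 <- nearest_band(refl$wavelengths, 670)
  d <- refl$values[, , b550] - refl$values[, , b670]
  expect_gt(mean(d[sc$truth$stalk_mask]), 0.04)
  expect_lt(mean(d[sc$truth$fruit_mask$grid]), 0.02)
})

test_that("an image too small for the requested fruits errors", {
  expect_error(generate_scene(scene_spec(rows = 10, cols = 10, n_fruits = 6,
                                         wavelengths = c(500, 600))),
               "too small")
})

test_that("study design: counts, stage ordering, and reproducibility", {
  st <- generate_study(n_per_variety = 3, seed = 42, rows = 40, cols = 40,
                       n_fruits = 1,
                       wavelengths = seq(450, 1050, length.out = 20))
  expect_equal(nrow(st$design), 6)
  expect_equal(as.vector(table(st$design$variety)), c(3L, 3L))
  st2 <- generate_study(n_per_variety = 3, seed = 42, rows = 40, cols = 40,
                        n_fruits = 1,
                        wavelengths = seq(450, 1050, length.out = 20))
  expect_identical(st$reference, st2$reference)
  expect_error(generate_study(n_per_variety = 4), "divisible")
})

test_that("stage means increase with maturity and variety A > B, by design", {
  st <- generate_study(n_per_variety = 30, seed = 7, rows = 40, cols = 40,
                       n_fruits = 1,
                       wavelengths = seq(450, 1050, length.out = 20))
  agg <- aggregate(true_content ~ variety + stage, st$reference, mean)
  for (v in c("A", "B")) {
    m <- agg$true_content[agg$variety == v][order(agg$stage[agg$variety == v])]
    expect_true(all(diff(m) > 0))
  }
  for (s in c("S1", "S2", "S3"))
    expect_gt(agg$true_content[agg$variety == "A" & agg$stage == s],
              agg$true_content[agg$variety == "B" & agg$stage == s])
})

test_that("wet chemistry applied to emitted absorbances recovers true content", {
  # zero measurement noise: exact round-trip through Eq.-style formulas
  st0 <- generate_study(n_per_variety = 3, seed = 1, noise_sd_absorbance = 0,
                        rows = 40, cols = 40, n_fruits = 1,
                        wavelengths = seq(450, 1050, length.out = 20))
  A <- differential_absorbance(st0$reference$a520_ph1, st0$reference$a700_ph1,
                               st0$reference$a520_ph45, st0$reference$a700_ph45)
  got <- anthocyanin_content(A, chem_constants(M = st0$reference$mass_g))
  expect_equal(got, st0$reference$true_content, tolerance = 1e-9)
  # with noise: recovery within a few sd of the injected absorbance noise
  st1 <- generate_study(n_per_variety = 30, seed = 2,
                        noise_sd_absorbance = 0.005,
                        rows = 40, cols = 40, n_fruits = 1,
                        wavelengths = seq(450, 1050, length.out = 20))
  resid <- st1$reference$content_mg_g - st1$reference$true_content
  sd_content <- 0.005 * 449.2 * 25 * 10 / (26900 * 0.5)
  expect_lt(max(abs(resid)), 4 * sd_content)
  expect_gt(sd(resid), sd_content / 3)
})
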