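# small fitted bundle over a toy scene, shared by several blocks
local_toy_bundle <- function(selector = NULL) {
  spec <- small_scene_spec(seed = 101, anthocyanin_mean = 2)
  sc <- generate_scene(spec)
  refl <- calibrate(sc$raw, sc$white, sc$dark)
  mask <- remove_stalk(refl, segment_fruit(refl))
  # train a tiny linear-ish model on pixels of this very scene
  px <- sample_pixels(refl, mask, n = 300, seed = 5)
  idx <- as.integer(sub("px_", "", px$row_ids))
  y <- sc$truth$concentration_map[idx]
  feats <- snv(crop_window(px))
  model <- fit_elm(feats$values, y, n_hidden = 30, seed = 2)
  list(bundle = model_bundle(model, feats$wavelengths, selector = selector),
       refl = refl, mask = mask, truth = sc$truth)
}

test_that("map statistics: truth against itself and a constant offset", {
  spec <- small_scene_spec(seed = 102)
  sc <- generate_scene(spec)
  tr <- sc$truth
  pm <- structure(list(values = ifelse(tr$fruit_mask$grid,
                                       tr$concentration_map, NA),
                       mask = tr$fruit_mask,
                       range = range(tr$concentration_map[tr$fruit_mask$grid])),
                  class = "prediction_map")
  st <- map_statistics(pm, tr)
  expect_equal(st$r2, 1)
  expect_equal(st$rmse, 0)
  pm$values <- pm$values + 0.1
  st2 <- map_statistics(pm, tr)
  expect_equal(st2$rmse, 0.1, tolerance = 1e-12)
  expect_equal(st2$mean_error, 0.1, tolerance = 1e-12)
})

test_that("predict_map fills exactly the mask and recovers pixel structure", {
  tb <- local_toy_bundle()
  pm <- predict_map(tb$refl, tb$mask, tb$bundle)
  expect_true(all(is.finite(pm$values[tb$mask$grid])))
  expect_true(all(is.na(pm$values[!tb$mask$grid])))
  expect_equal(dim(pm$values), dim(tb$mask$grid))
  st <- map_statistics(pm, tb$truth)
  expect_gt(st$r2, 0.5)   # in-scene model: map tracks the truth field
  # mean over mask close to the truth mean
  expect_lt(abs(st$mean_error), 0.1)
})

test_that("mapping is pixel-order invariant (restricting the mask is consistent)", {
  tb <- local_toy_bundle()
  pm_full <- predict_map(tb$refl, tb$mask, tb$bundle)
  g <- tb$mask$grid
  idx_on <- which(g)
  half <- fruit_mask(matrix(replace(rep(FALSE, length(g)),
                                    idx_on[seq(1, length(idx_on), by = 2)],
                                    TRUE),
                            nrow(g), ncol(g)))
  pm_half <- predict_map(tb$refl, half, tb$bundle)
  expect_equal(pm_half$values[half$grid], pm_full$values[half$grid])
})

test_that("per-pixel predictions averaged over the ROI track the ROI-mean prediction", {
  tb <- local_toy_bundle()
  pm <- predict_map(tb$refl, tb$mask, tb$bundle)
  roi_mean <- mean_spectrum(tb$refl, tb$mask)
  mean_pred <- predict_bundle(tb$bundle, roi_mean)
  expect_lt(abs(mean(pm$values[tb$mask$grid]) - mean_pred), 0.2)
})

test_that("rendering is deterministic, clips only in the legend, and writes a PNG", {
  tb <- local_toy_bundle()
  pm <- predict_map(tb$refl, tb$mask, tb$bundle)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.png"); f2 <- file.path(dir, "b.png")
  before <- pm$values
  render_map(pm, f1, scale = c(1.8, 2.2))
  render_map(pm, f2, scale = c(1.8, 2.2))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(pm$values, before)   # rendering never mutates the data
  expect_gt(file.size(f1), 200)
  expect_error(render_map(pm, f1, scale = c(2, 2)), "scale")
})

test_that("bundle/cube wavelength mismatch raises an alignment error", {
  tb <- local_toy_bundle()
  bad <- model_bundle(tb$bundle$model,
                      tb$bundle$wavelengths + 5,  # > 2 nm off
                      selector = NULL)
  expect_error(predict_map(tb$refl, tb$mask, bad), "wavelengths")
})
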