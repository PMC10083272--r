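test_that("the default architecture encodes 379-band spectra to 13 features", {
  set.seed(81)
  X <- toy_pixel_spectra(n = 240, p = 379, seed = 81)
  m <- train_sae(X, epochs = 2, batch = 40, seed = 1)
  expect_equal(m$layer_sizes, c(379, 300, 150, 13, 150, 300, 379))
  enc <- sae_encode(m, X[1:5, ])
  expect_equal(dim(enc), c(5, 13))
})

test_that("training reduces reconstruction loss and is seed-reproducible", {
  X <- toy_pixel_spectra(n = 300, p = 60, seed = 82)
  m <- train_sae(X, h = 6, hidden = c(30, 15), epochs = 15, batch = 50,
                 seed = 7)
  ft <- m$loss$finetune
  expect_length(ft, 15)
  expect_lt(ft[length(ft)], ft[1])
  m2 <- train_sae(X, h = 6, hidden = c(30, 15), epochs = 15, batch = 50,
                  seed = 7)
  expect_identical(m$loss$finetune, m2$loss$finetune)
  expect_identical(m$W, m2$W)
})

test_that("encodings are row-independent with entries in (0, 1)", {
  X <- toy_pixel_spectra(n = 100, p = 40, seed = 83)
  m <- train_sae(X, h = 4, hidden = c(20, 10), epochs = 5, batch = 25,
                 seed = 2)
  e_all <- sae_encode(m, X[1:2, ])
  e_one <- sae_encode(m, X[1, , drop = FALSE])
  expect_equal(e_all[1, ], e_one[1, ], tolerance = 1e-12)
  expect_true(all(e_all > 0 & e_all < 1))
})

test_that("reconstructed pixel spectra are nearly coincident with the originals", {
  # pixels from two synthetic scenes at different maturity: the deep
  # features must reconstruct the SNV spectra almost perfectly
  px <- do.call(rbind, lapply(c(1, 3), function(i) {
    sc <- generate_scene(small_scene_spec(seed = i, anthocyanin_mean = i,
                                          c_chl = c(0.8, 0, 0.15)[i]))
    refl <- calibrate(sc$raw, sc$white, sc$dark)
    mask <- remove_stalk(refl, segment_fruit(refl))
    sample_pixels(refl, mask, 400, seed = i)$values
  }))
  X <- snv(spectral_matrix(px, seq(450, 1050, length.out = 80)))$values
  m <- train_sae(X, h = 6, hidden = c(40, 20), epochs = 30, batch = 50,
                 seed = 3)
  R <- sae_reconstruct(m, X)
  cors <- vapply(seq_len(nrow(X)), function(i) cor(R[i, ], X[i, ]),
                 numeric(1))
  expect_gt(median(cors), 0.95)
  # deep features separate maturity stages: between-stage distances exceed
  # within-stage distances on average
  E <- sae_encode(m, X)
  g1 <- 1:400; g2 <- 401:800
  centroid_dist <- sqrt(sum((colMeans(E[g1, ]) - colMeans(E[g2, ]))^2))
  within <- mean(c(sqrt(rowSums(sweep(E[g1, ], 2, colMeans(E[g1, ]))^2)),
                   sqrt(rowSums(sweep(E[g2, ], 2, colMeans(E[g2, ]))^2))))
  expect_gt(centroid_dist, within)
})

test_that("a latent layer wider than its predecessor is rejected", {
  X <- toy_pixel_spectra(n = 50, p = 30, seed = 85)
  expect_error(train_sae(X, h = 20, hidden = c(15, 10)), "smaller")
})

test_that("encoding rejects inputs on the wrong band grid", {
  X <- toy_pixel_spectra(n = 60, p = 30, seed = 86)
  m <- train_sae(X, h = 3, hidden = c(15, 8), epochs = 2, batch = 20, seed = 1)
  expect_error(sae_encode(m, X[, 1:10]), "expects")
})
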