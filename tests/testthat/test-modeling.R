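test_that("stratified split: 6 cells of 30 give 126/54 and a clean partition", {
  strata <- rep(paste(rep(c("A", "B"), each = 3), c("S1", "S2", "S3")),
                each = 30)
  sp <- split_dataset(180, strata, 0.7, seed = 1)
  expect_length(sp$train, 126)
  expect_length(sp$test, 54)
  expect_setequal(c(sp$train, sp$test), 1:180)
  expect_length(intersect(sp$train, sp$test), 0)
  # each cell splits 21/9
  for (s in unique(strata))
    expect_equal(sum(sp$train %in% which(strata == s)), 21)
})

test_that("a single 10-sample stratum splits 7/3; tiny strata go to training", {
  sp <- split_dataset(10, NULL, 0.7, seed = 2)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  strata <- c(rep("big", 11), "lonely")
  expect_warning(sp2 <- split_dataset(12, strata, 0.7, seed = 3), "lonely")
  expect_true(12 %in% sp2$train)
})

test_that("splits are deterministic given the seed", {
  expect_identical(split_dataset(30, NULL, 0.7, seed = 5),
                   split_dataset(30, NULL, 0.7, seed = 5))
  expect_false(identical(split_dataset(30, NULL, 0.7, seed = 5)$train,
                         split_dataset(30, NULL, 0.7, seed = 6)$train))
})

test_that("evaluation matches hand arithmetic and definitional cases", {
  # y=(1,2,3), yhat=(1,2,4): RMSE = sqrt(1/3), R2 = 1 - 1/2 = 0.5
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  # perfect predictions
  expect_equal(r_squared(1:5, 1:5), 1)
  expect_equal(rmse(1:5, 1:5), 0)
  # predicting the mean gives R2 = 0
  expect_equal(r_squared(c(2, 4, 6), rep(4, 3)), 0)
  # zero-variance observations: undefined marker
  expect_true(is.na(r_squared(rep(1, 4), rep(1, 4))))
})

test_that("evaluate_model reports both sets through a fitted model", {
  d <- lin_data(60, 3, 1:3, c(1, 2, -1), noise_sd = 0.05, seed = 71)
  tr <- 1:40; te <- 41:60
  fit <- fit_elm(d$X[tr, ], d$y[tr], n_hidden = 25, seed = 1)
  rep <- evaluate_model(fit, d$X[tr, ], d$y[tr], d$X[te, ], d$y[te])
  expect_gt(rep$r2_train, 0.95)
  expect_gt(rep$r2_test, 0.9)
  expect_lte(rep$r2_train, 1)
  expect_gte(rep$rmse_test, 0)
  expect_equal(rep$n_train, 40)
  expect_equal(rep$n_test, 20)
})

test_that("GA-optimized ELM beats the median random-weight ELM in CV RMSE", {
  d <- lin_data(60, 4, c(1, 3), c(2, -1), noise_sd = 0.1, seed = 72)
  ga_fit <- fit_ga_elm(d$X, d$y, n_hidden = 12, generations = 15,
                       population = 12, seed = 4)
  expect_true(all(diff(ga_fit$ga$path) <= 0))
  cv_of <- function(seed) {
    W <- matrix(runif(4 * 12, -1, 1), 4, 12)
    b <- runif(12, -1, 1)
    # same 5-fold CV criterion as the GA fitness
    folds <- withr::with_seed(4 + 1, sample(rep(1:5, length.out = 60)))
    Xs <- anthomap:::apply_scaling(d$X, anthomap:::minmax_scaling(d$X))
    H <- anthomap:::sigmoid(Xs %*% W + rep(b, each = 60))
    press <- 0
    for (f in 1:5) {
      tr <- folds != f
      beta <- qr.coef(qr(H[tr, ]), d$y[tr]); beta[is.na(beta)] <- 0
      press <- press + sum((d$y[!tr] - H[!tr, ] %*% beta)^2)
    }
    sqrt(press / 60)
  }
  set.seed(99)
  rand_cv <- replicate(20, cv_of())
  expect_lte(ga_fit$ga$fitness, median(rand_cv))
})

test_that("GA-optimized LS-SVM returns hyperparameters within bounds", {
  d <- lin_data(40, 2, 1:2, c(1, 1), noise_sd = 0.1, seed = 73)
  ga_fit <- fit_ga_lssvm(d$X, d$y, generations = 10, population = 10,
                         seed = 2)
  expect_gte(ga_fit$model$C, 0.01)
  expect_lte(ga_fit$model$C, 100)
  expect_gte(ga_fit$model$gamma, 0.01)
  expect_lte(ga_fit$model$gamma, 100)
  expect_true(all(diff(ga_fit$ga$path) <= 0))
  rep <- evaluate_model(ga_fit, d$X, d$y, d$X, d$y)
  expect_gt(rep$r2_train, 0.8)
})
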