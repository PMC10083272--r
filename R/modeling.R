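#' Stratified 7:3 train/test split
#'
#' Splits samples into disjoint, exhaustive train and test sets so that
#' each stratum (e.g. variety x stage cell) splits as close to the target
#' fraction as integer rounding allows. A stratum with fewer than 2
#' members goes wholly to training with a warning.
#'
#' @param n number of samples, or a vector whose length is used.
#' @param strata factor/character vector of stratum labels (length n);
#'   `NULL` treats all samples as one stratum.
#' @param train_fraction fraction assigned to training.
#' @param seed integer seed.
#' @return List with integer vectors `train` and `test` (indices).
#' @export
split_dataset <- function(n, strata = NULL, train_fraction = 0.7, seed = 1L) {
  if (length(n) > 1) n <- length(n)
  stopifnot(n >= 10)
  if (is.null(strata)) strata <- rep("all", n)
  stopifnot(length(strata) == n)
  with_seed(seed, {
    train <- integer(0)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      if (length(idx) < 2) {
        warning("stratum '", s, "' has < 2 members; assigned to training")
        train <- c(train, idx)
        next
      }
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Fit an ELM with genetic-algorithm-optimized hidden weights
#'
#' The genome concatenates the `d x n_hidden` input weights and the
#' `n_hidden` offsets, all bounded in [-1, 1]. Fitness is the k-fold
#' cross-validated RMSE on the training set (training RMSE would trivially
#' favor interpolating ELMs). The returned model is refit on all training
#' rows with the best genome.
#'
#' When `pixel_val` is supplied (features of individual ROI pixels from
#' training scenes plus each pixel's scene-level reference content), the
#' final solve additionally selects a ridge penalty on the output
#' weights by minimizing the RMSE of per-pixel predictions against the
#' scene references. Sample-level cross-validation cannot detect
#' instability off the training manifold — a near-interpolating ELM can
#' carry enormous output weights that explode under per-pixel sensor
#' noise — so the deployment distribution itself picks the penalty. Only
#' training scenes are used.
#'
#' @param X training features, n x d.
#' @param y training response.
#' @param n_hidden hidden neurons.
#' @param generations GA generations.
#' @param population GA population size.
#' @param folds CV folds for the fitness.
#' @param seed integer seed.
#' @param pixel_val optional list with `features` (m x d matrix, pixel
#'   features) and `y_scene` (length m, each pixel's scene reference
#'   content, mg/g) used to select the output-weight ridge penalty.
#' @param ridge_grid candidate ridge penalties (0 is always included).
#' @return List: `model` (an `elm_model`), `ga` (best fitness + path),
#'   `ridge` (selected penalty).
#' @export
fit_ga_elm <- function(X, y, n_hidden = 90, generations = 300,
                       population = 20, folds = 5, seed = 1L,
                       pixel_val = NULL, ridge_grid = 10^seq(-6, 2, 0.5)) {
  X <- as.matrix(X); y <- as.numeric(y)
  d <- ncol(X); n <- nrow(X)
  scaling <- minmax_scaling(X)
  Xs <- apply_scaling(X, scaling)
  assign_f <- with_seed(seed + 1L, sample(rep(seq_len(folds), length.out = n)))
  fitness <- function(genome) {
    W <- matrix(genome[seq_len(d * n_hidden)], d, n_hidden)
    b <- genome[d * n_hidden + seq_len(n_hidden)]
    H <- sigmoid(Xs %*% W + rep(b, each = n))
    press <- 0
    for (f in seq_len(folds)) {
      tr <- assign_f != f
      # QR least squares; folds are taller than the hidden layer in
      # practice, and rank-deficient (aliased) columns drop to zero
      ym <- mean(y[tr])
      beta <- qr.coef(qr(H[tr, , drop = FALSE]), y[tr] - ym)
      beta[is.na(beta)] <- 0
      pred <- H[!tr, , drop = FALSE] %*% beta + ym
      press <- press + sum((y[!tr] - pred)^2)
    }
    sqrt(press / n)
  }
  cfg <- ga_config(population = population, generations = generations,
                   lower = rep(-1, d * n_hidden + n_hidden),
                   upper = rep(1, d * n_hidden + n_hidden), seed = seed)
  ga <- ga_optimize(fitness, cfg)
  W <- matrix(ga$genome[seq_len(d * n_hidden)], d, n_hidden)
  b <- ga$genome[d * n_hidden + seq_len(n_hidden)]
  ridge <- 0
  if (!is.null(pixel_val)) {
    H <- sigmoid(Xs %*% W + rep(b, each = n))
    Xp <- apply_scaling(as.matrix(pixel_val$features), scaling)
    Hp <- sigmoid(Xp %*% W + rep(b, each = nrow(Xp)))
    sv <- svd(H)
    uy <- crossprod(sv$u, y - mean(y))
    px_rmse <- vapply(c(0, ridge_grid), function(lam) {
      fac <- if (lam > 0) sv$d / (sv$d^2 + lam) else
        ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)
      beta <- sv$v %*% (uy * fac)
      rmse(pixel_val$y_scene, Hp %*% beta + mean(y))
    }, numeric(1))
    ridge <- c(0, ridge_grid)[which.min(px_rmse)]
  }
  model <- fit_elm(X, y, n_hidden = n_hidden, input_weights = W, offsets = b,
                   scaling = scaling, ridge = ridge)
  list(model = model, ga = ga[c("fitness", "path")], ridge = ridge)
}

#' Fit an LS-SVM with genetic-algorithm-optimized (C, gamma)
#'
#' Genome `(C, gamma)` bounded in [0.01, 100]^2; fitness is the k-fold
#' cross-validated RMSE on the training set. The returned model is refit
#' on the full training set at the best hyperparameters.
#'
#' @inheritParams fit_ga_elm
#' @param bounds length-2 list or vector `c(lower, upper)` shared by C and
#'   gamma.
#' @return List: `model` (an `lssvm_model`), `ga` (best fitness + path).
#' @export
fit_ga_lssvm <- function(X, y, generations = 200, population = 20, folds = 5,
                         bounds = c(0.01, 100), seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  scaling <- minmax_scaling(X)
  assign_f <- with_seed(seed + 1L, sample(rep(seq_len(folds), length.out = n)))
  fitness <- function(genome) {
    press <- 0
    for (f in seq_len(folds)) {
      tr <- assign_f != f
      fit <- fit_lssvm(X[tr, , drop = FALSE], y[tr],
                       C = genome[1], gamma = genome[2], scaling = scaling)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      press <- press + sum((y[!tr] - pred)^2)
    }
    sqrt(press / n)
  }
  cfg <- ga_config(population = population, generations = generations,
                   lower = rep(bounds[1], 2), upper = rep(bounds[2], 2),
                   seed = seed)
  ga <- ga_optimize(fitness, cfg)
  model <- fit_lssvm(X, y, C = ga$genome[1], gamma = ga$genome[2],
                     scaling = scaling)
  list(model = model, ga = ga[c("fitness", "path")])
}

#' Evaluate a regression model on training and testing sets
#'
#' Reports the determination coefficients R2c/R2p (`1 - SS_res/SS_tot`,
#' with SS_tot about the evaluated set's own mean) and the root mean
#' square errors RMSEC/RMSEP. Squared Pearson correlations are exported
#' alongside. A zero-variance response yields `NA` for that set's R2.
#'
#' @param model a fitted model with a `predict` method (or a `ga_*` result
#'   list holding one under `$model`).
#' @param X_train,y_train,X_test,y_test the split data.
#' @return List of class `eval_report`: `r2_train`, `r2_test`,
#'   `rmse_train`, `rmse_test`, `cor2_train`, `cor2_test`, `n_train`,
#'   `n_test`.
#' @export
evaluate_model <- function(model, X_train, y_train, X_test, y_test) {
  if (is.list(model) && !is.null(model$model) && is.null(attr(model, "class")))
    model <- model$model
  stopifnot(length(y_train) > 0, length(y_test) > 0)
  pt <- predict(model, as.matrix(X_train))
  pp <- predict(model, as.matrix(X_test))
  structure(list(
    r2_train = r_squared(y_train, pt),
    r2_test = r_squared(y_test, pp),
    rmse_train = rmse(y_train, pt),
    rmse_test = rmse(y_test, pp),
    cor2_train = safe_cor2(y_train, pt),
    cor2_test = safe_cor2(y_test, pp),
    n_train = length(y_train), n_test = length(y_test)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> R2c=%.4f RMSEC=%.4f | R2p=%.4f RMSEP=%.4f (n=%d/%d)\n",
              x$r2_train, x$rmse_train, x$r2_test, x$rmse_test,
              x$n_train, x$n_test))
  invisible(x)
}

#' Determination coefficient and RMSE
#'
#' `r_squared` is `1 - SS_res / SS_tot` about the observed mean (`NA` when
#' the observations have zero variance); `rmse` is the root mean squared
#' residual.
#'
#' @param obs,pred observed and predicted values.
#' @return A scalar.
#' @export
r_squared <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot < 1e-300) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

#' @rdname r_squared
#' @export
rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

safe_cor2 <- function(a, b) {
  if (stats::sd(a) < 1e-300 || stats::sd(b) < 1e-300) return(NA_real_)
  stats::cor(a, b)^2
}
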