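#' Partial least squares regression (PLS1, SIMPLS)
#'
#' Compact single-response SIMPLS used as the regression engine inside
#' competitive adaptive reweighted sampling, where the absolute PLS
#' regression coefficients drive variable retention. Components whose
#' score norm collapses (rank exhausted) are dropped silently.
#'
#' @param X numeric matrix, n x p.
#' @param y numeric response, length n.
#' @param ncomp number of latent components requested.
#' @return List of class `pls1_model`: `coef` (p), `intercept`, `ncomp`
#'   (components actually extracted), `x_mean`, `y_mean`.
#' @export
pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2)
  ncomp <- min(ncomp, p, n - 1)
  mu <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, mu); yc <- y - ym
  S <- crossprod(Xc, yc)                      # p x 1
  R <- matrix(0, p, ncomp); V <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    r <- S
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (!is.finite(nt) || nt < 1e-10) break
    t <- t / nt; r <- r / nt
    pvec <- crossprod(Xc, t)
    Q[a] <- sum(yc * t)
    v <- pvec
    if (a > 1) {
      Va <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Va %*% crossprod(Va, pvec)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; V[, a] <- v
    a_used <- a
  }
  if (a_used == 0L) {
    coef <- numeric(p)
  } else {
    coef <- R[, seq_len(a_used), drop = FALSE] %*% Q[seq_len(a_used)]
  }
  structure(list(coef = as.numeric(coef),
                 intercept = ym - sum(mu * coef),
                 ncomp = a_used, x_mean = mu, y_mean = ym),
            class = "pls1_model")
}

#' @rdname pls1_fit
#' @param object a `pls1_model`.
#' @param newdata matrix of predictors.
#' @param ... unused.
#' @export
predict.pls1_model <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$coef + object$intercept)
}

# k-fold CV RMSE of a PLS1 model on X[, cols] (deterministic fold layout)
cv_rmse_pls <- function(X, y, cols = seq_len(ncol(X)), folds = 10, ncomp = 10,
                        seed = 1L) {
  n <- length(y)
  folds <- min(folds, n)
  assign_f <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  press <- 0
  for (f in seq_len(folds)) {
    tr <- assign_f != f
    nc <- min(ncomp, length(cols), sum(tr) - 1)
    fit <- pls1_fit(X[tr, cols, drop = FALSE], y[tr], nc)
    pred <- predict(fit, X[!tr, cols, drop = FALSE])
    press <- press + sum((y[!tr] - pred)^2)
  }
  sqrt(press / n)
}
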