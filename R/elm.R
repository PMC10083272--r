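#' Extreme learning machine regression
#'
#' Single-hidden-layer feedforward network whose hidden weights and
#' offsets are fixed (random, or supplied — e.g. by a genetic algorithm)
#' and whose output weights are solved in closed form as the minimum-norm
#' least-squares solution `beta = pinv(H) (y - mean(y))`,
#' `H = sigmoid(X W + b)`; predictions add the stored response mean back.
#' There is no iterative training. Inputs are min-max scaled per column
#' to [-1, 1] internally (ranges stored in the model) so the sigmoid
#' operates in its active region; the response centering means the hidden
#' layer only has to represent deviations from the mean response.
#'
#' @param X numeric matrix of features, n x d.
#' @param y numeric response, length n.
#' @param n_hidden hidden neurons.
#' @param input_weights optional d x n_hidden matrix in [-1, 1]; random if
#'   `NULL`.
#' @param offsets optional n_hidden offsets in [-1, 1]; random if `NULL`.
#' @param seed seed for random weights when not supplied.
#' @param scaling optional precomputed scaling (list `lo`, `hi`); computed
#'   from `X` if `NULL`.
#' @param ridge ridge penalty on the output weights (0 = exact
#'   minimum-norm least squares). A positive penalty trades a little
#'   training fit for bounded weights, which matters when the model is
#'   applied off the training manifold (e.g. per-pixel mapping).
#' @return List of class `elm_model`.
#' @export
fit_elm <- function(X, y, n_hidden = 90, input_weights = NULL, offsets = NULL,
                    seed = 1L, scaling = NULL, ridge = 0) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite features or response", call. = FALSE)
  d <- ncol(X)
  if (is.null(input_weights) || is.null(offsets)) {
    rnd <- with_seed(seed, stats::runif(d * n_hidden + n_hidden, -1, 1))
    if (is.null(input_weights))
      input_weights <- matrix(rnd[seq_len(d * n_hidden)], d, n_hidden)
    if (is.null(offsets))
      offsets <- rnd[d * n_hidden + seq_len(n_hidden)]
  }
  stopifnot(identical(dim(input_weights), c(d, as.integer(n_hidden))) ||
            all(dim(input_weights) == c(d, n_hidden)),
            length(offsets) == n_hidden)
  if (is.null(scaling)) scaling <- minmax_scaling(X)
  Xs <- apply_scaling(X, scaling)
  H <- sigmoid(Xs %*% input_weights + rep(offsets, each = nrow(Xs)))
  # the response is centered before the solve: the hidden layer then only
  # has to span deviations from the mean, not the mean itself
  y_mean <- mean(y)
  beta <- if (ridge > 0) ridge_solve(H, y - y_mean, ridge)
          else pinv_solve(H, y - y_mean)
  structure(list(input_weights = input_weights, offsets = offsets,
                 output_weights = beta, y_mean = y_mean,
                 n_hidden = n_hidden, scaling = scaling, ridge = ridge),
            class = "elm_model")
}

#' @rdname fit_elm
#' @param object an `elm_model`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @export
predict.elm_model <- function(object, newdata, ...) {
  Xs <- apply_scaling(as.matrix(newdata), object$scaling)
  H <- sigmoid(Xs %*% object$input_weights +
                 rep(object$offsets, each = nrow(Xs)))
  as.numeric(H %*% object$output_weights) + object$y_mean
}

sigmoid <- function(z) 1 / (1 + exp(-z))

minmax_scaling <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  flat <- hi - lo < 1e-12
  hi[flat] <- lo[flat] + 1
  list(lo = lo, hi = hi)
}

apply_scaling <- function(X, s) {
  2 * sweep(sweep(X, 2, s$lo), 2, s$hi - s$lo, "/") - 1
}

# minimum-norm least-squares via SVD (Moore-Penrose)
pinv_solve <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d, 1e-300)
  as.numeric(sv$v[, pos, drop = FALSE] %*%
               ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos]))
}

# ridge solution via the same SVD: beta = V d/(d^2 + lambda) U' b
ridge_solve <- function(A, b, lambda) {
  sv <- svd(A)
  as.numeric(sv$v %*% (crossprod(sv$u, b) * sv$d / (sv$d^2 + lambda)))
}
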