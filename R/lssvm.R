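#' Least-squares support vector machine regression (RBF kernel)
#'
#' Solves the standard LS-SVM regression linear system over the RBF
#' kernel matrix `K[i,j] = exp(-gamma ||x_i - x_j||^2)`:
#'
#' \preformatted{ [ 0   1'          ] [ b     ]   [ 0 ]
#'  [ 1   K + I / C  ] [ alpha ] = [ y ]}
#'
#' Regularization `C` trades training fit against smoothness; `gamma` is
#' the kernel width parameter. Inputs are min-max scaled per column to
#' [-1, 1] internally. If the system is numerically singular a jitter of
#' 1e-10 is added to the diagonal once before giving up.
#'
#' @param X numeric feature matrix, n x d.
#' @param y numeric response, length n.
#' @param C regularization parameter (> 0).
#' @param gamma RBF width parameter (> 0).
#' @param scaling optional precomputed min-max scaling.
#' @return List of class `lssvm_model` (support values `alpha`, `bias`,
#'   scaled training inputs, `C`, `gamma`).
#' @export
fit_lssvm <- function(X, y, C = 10, gamma = 1, scaling = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), C > 0, gamma > 0)
  if (is.null(scaling)) scaling <- minmax_scaling(X)
  Xs <- apply_scaling(X, scaling)
  n <- nrow(Xs)
  K <- rbf_kernel(Xs, Xs, gamma)
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(1 / C, n)))
  rhs <- c(0, y)
  sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    M2 <- M; diag(M2)[-1] <- diag(M2)[-1] + 1e-10
    sol <- solve(M2, rhs)   # errors if still singular
  }
  structure(list(alpha = sol[-1], bias = sol[1], X_train = Xs,
                 C = C, gamma = gamma, scaling = scaling),
            class = "lssvm_model")
}

#' @rdname fit_lssvm
#' @param object an `lssvm_model`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @export
predict.lssvm_model <- function(object, newdata, ...) {
  Xs <- apply_scaling(as.matrix(newdata), object$scaling)
  K <- rbf_kernel(Xs, object$X_train, object$gamma)
  as.numeric(K %*% object$alpha + object$bias)
}

rbf_kernel <- function(A, B, gamma) {
  sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sq[sq < 0] <- 0
  exp(-gamma * sq)
}
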