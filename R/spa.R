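#' Successive projections algorithm for wavelength selection
#'
#' Forward selection that minimizes collinearity: starting from each
#' candidate column, a chain is grown by repeatedly projecting all
#' remaining columns onto the orthogonal complement of the already-chosen
#' set and adding the column with the largest projection norm. Every
#' (start, k) subset is then scored by the RMSE of an ordinary
#' least-squares fit evaluated on a held-out validation split; the subset
#' with minimum validation RMSE wins. The RMSE-vs-k path of the winning
#' start typically decreases in a ladder shape then levels off.
#'
#' @param X a [spectral_matrix()] or numeric matrix, n x p.
#' @param y numeric response (reference contents, mg/g), length n.
#' @param max_vars maximum chain length (capped at p and at what the
#'   validation split can support).
#' @param validation fraction of rows held out for scoring.
#' @param seed integer seed controlling the split.
#' @return List of class `selection_result`: `method = "SPA"`, `indices`
#'   (sorted ascending), `wavelengths` (if available), `diagnostics`
#'   (`rmse_path` over k for the winning start, `best_k`, `best_start`,
#'   `best_rmse`).
#' @export
spa_select <- function(X, y, max_vars = 25, validation = 1 / 3, seed = 1L) {
  wl <- NULL
  if (inherits(X, "spectral_matrix")) { wl <- X$wavelengths; X <- X$values }
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  n_val <- max(1L, round(validation * n))
  val <- with_seed(seed, sample(n, n_val))
  tr <- setdiff(seq_len(n), val)
  max_vars <- min(max_vars, p, length(tr) - 2L)
  if (max_vars < 1L) stop("too few training rows for SPA", call. = FALSE)

  Xtr <- X[tr, , drop = FALSE]
  mu <- colMeans(Xtr)
  Xc <- sweep(Xtr, 2, mu)

  chains <- matrix(0L, p, max_vars)
  for (start in seq_len(p)) {
    chain <- spa_chain(Xc, start, max_vars)
    chains[start, seq_along(chain)] <- chain
  }

  score <- function(cols) {
    fit <- stats::.lm.fit(cbind(1, X[tr, cols, drop = FALSE]), y[tr])
    pred <- cbind(1, X[val, cols, drop = FALSE]) %*% fit$coefficients
    sqrt(mean((y[val] - pred)^2))
  }
  best <- list(rmse = Inf)
  rmse_by_start <- vector("list", p)
  for (start in seq_len(p)) {
    chain <- chains[start, ]
    chain <- chain[chain > 0L]
    rp <- vapply(seq_along(chain), function(k) score(chain[seq_len(k)]),
                 numeric(1))
    rmse_by_start[[start]] <- rp
    k_best <- which.min(rp)
    if (rp[k_best] < best$rmse)
      best <- list(rmse = rp[k_best], start = start, k = k_best,
                   cols = chain[seq_len(k_best)])
  }
  idx <- sort(best$cols)
  structure(list(
    method = "SPA",
    indices = idx,
    wavelengths = if (!is.null(wl)) wl[idx] else NULL,
    diagnostics = list(rmse_path = rmse_by_start[[best$start]],
                       best_k = best$k, best_start = best$start,
                       best_rmse = best$rmse)
  ), class = "selection_result")
}

# Grow one projection chain: starting from column `start`, repeatedly
# project the remaining columns onto the orthogonal complement of the
# chosen set and append the column with the largest projection norm.
spa_chain <- function(Xc, start, max_vars) {
  Z <- Xc
  chain <- integer(max_vars)
  chain[1] <- start
  len <- 1L
  for (k in seq_len(max_vars - 1L)) {
    u <- Z[, chain[k]]
    uu <- sum(u^2)
    if (uu < 1e-12) { warning("SPA chain truncated (degenerate column)"); break }
    Z <- Z - u %*% (crossprod(u, Z) / uu)
    norms <- colSums(Z^2)
    norms[chain[seq_len(k)]] <- -Inf
    nxt <- which.max(norms)
    if (norms[nxt] < 1e-12) { warning("SPA chain truncated (collinear set)"); break }
    chain[k + 1L] <- nxt
    len <- k + 1L
  }
  chain[seq_len(len)]
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d variable(s)%s\n", x$method,
              if (x$method == "SAE") x$h else length(x$indices),
              if (!is.null(x$wavelengths))
                paste0(" @ ", paste(round(x$wavelengths, 1), collapse = ", "), " nm")
              else ""))
  invisible(x)
}
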