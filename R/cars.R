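#' Competitive adaptive reweighted sampling for wavelength selection
#'
#' Monte-Carlo variable selection driven by absolute PLS regression
#' coefficients. Each of `n_runs` runs (i) draws a random calibration
#' subset (`calib_frac` of the samples), (ii) fits PLS1 on the currently
#' surviving variables, (iii) applies the exponentially decreasing
#' function (EDF) — the retained fraction falls from 1 at run 1 to `2/p`
#' at the final run — keeping the variables with the largest
#' |coefficient|, (iv) competitively resamples among them with weights
#' proportional to |coefficient| (adaptive reweighted sampling), and
#' (v) records the k-fold cross-validated RMSE (RMSECV) of the surviving
#' set on the full data. The surviving set of the run with minimum RMSECV
#' is returned.
#'
#' @param X a [spectral_matrix()] or numeric matrix, n x p.
#' @param y numeric response, length n.
#' @param n_runs number of sampling runs.
#' @param cv_folds folds for the RMSECV evaluation.
#' @param seed integer seed.
#' @param calib_frac Monte-Carlo calibration fraction per run.
#' @param max_ncomp cap on PLS components; the per-run count is chosen by
#'   5-fold cross-validation on the calibration subset (and reduced
#'   whenever the surviving set is smaller).
#' @return List of class `selection_result`: `method = "CARS"`, `indices`,
#'   `wavelengths`, `diagnostics` (`rmsecv_path` and `retained_path`, one
#'   entry per run; `best_run`; `sets` per run).
#' @export
cars_select <- function(X, y, n_runs = 50, cv_folds = 10, seed = 1L,
                        calib_frac = 0.8, max_ncomp = 10) {
  wl <- NULL
  if (inherits(X, "spectral_matrix")) { wl <- X$wavelengths; X <- X$values }
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2 * cv_folds)

  # EDF: retained fraction r_i = exp(-k (i - 1)); r_1 = 1, r_{n_runs} = 2/p
  kdec <- log(p / 2) / (n_runs - 1)
  ratio <- exp(-kdec * (seq_len(n_runs) - 1))

  with_seed(seed, {
    current <- seq_len(p)
    retained_path <- integer(n_runs)
    rmsecv_path <- numeric(n_runs)
    sets <- vector("list", n_runs)
    n_cal <- max(2L, round(calib_frac * n))
    for (i in seq_len(n_runs)) {
      cal <- sample(n, n_cal)
      Xi <- X[cal, current, drop = FALSE]
      nc <- choose_ncomp(Xi, y[cal], max_ncomp)
      fit <- pls1_fit(Xi, y[cal], nc)
      w <- abs(fit$coef)
      n_keep <- min(length(current), max(2L, round(p * ratio[i])))
      retained_path[i] <- n_keep
      keep <- order(w, decreasing = TRUE)[seq_len(n_keep)]
      # adaptive reweighted sampling among the EDF survivors
      wk <- w[keep]
      if (sum(wk) <= 0) wk <- rep(1, length(keep))
      drawn <- unique(sample(keep, size = n_keep, replace = TRUE,
                             prob = wk / sum(wk)))
      current <- sort(current[drawn])
      sets[[i]] <- current
      rmsecv_path[i] <- cv_rmse_pls(X, y, cols = current, folds = cv_folds,
                                    ncomp = min(max_ncomp, length(current)),
                                    seed = sample.int(2^31 - 2, 1))
    }
    best <- which.min(rmsecv_path)
    idx <- sets[[best]]
    structure(list(
      method = "CARS",
      indices = idx,
      wavelengths = if (!is.null(wl)) wl[idx] else NULL,
      diagnostics = list(rmsecv_path = rmsecv_path,
                         retained_path = retained_path,
                         best_run = best, sets = sets)
    ), class = "selection_result")
  })
}

# pick the PLS component count (<= max_ncomp) by 5-fold CV
choose_ncomp <- function(X, y, max_ncomp) {
  nc_max <- min(max_ncomp, ncol(X), nrow(X) - 2)
  if (nc_max <= 1) return(1L)
  folds <- min(5L, nrow(X))
  assign_f <- sample(rep(seq_len(folds), length.out = nrow(X)))
  press <- numeric(nc_max)
  for (f in seq_len(folds)) {
    tr <- assign_f != f
    for (nc in seq_len(nc_max)) {
      fnc <- pls1_fit(X[tr, , drop = FALSE], y[tr], nc)
      pred <- predict(fnc, X[!tr, , drop = FALSE])
      press[nc] <- press[nc] + sum((y[!tr] - pred)^2)
    }
  }
  which.min(press)
}
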