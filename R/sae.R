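#' Train a stacked auto-encoder on pixel spectra
#'
#' Builds the mirror-symmetric stack `p-300-150-h-150-300-p` (all sigmoid)
#' in two phases: greedy layer-wise pretraining of the three
#' auto-encoders (p-300-p, then 300-150-300 on the first code, then
#' 150-h-150), followed by end-to-end fine-tuning of the full stack under
#' mean-squared reconstruction loss. Optimization is minibatch SGD with
#' momentum at a constant learning rate; training is deterministic given
#' `seed` (single-threaded, R-generated shuffles).
#'
#' Because every unit is sigmoid, the input spectra (typically SNV rows,
#' which are unbounded) are affinely squashed per band to [0.05, 0.95]
#' using ranges estimated from the training matrix; the squash is stored
#' in the model and replayed identically at encoding time.
#'
#' @param P a [spectral_matrix()] or numeric matrix of pixel spectra
#'   (rows = pixels), SNV-pretreated.
#' @param h latent code size (the number of deep spectral features).
#' @param hidden sizes of the two intermediate encoder layers.
#' @param epochs training epochs (used for each pretraining phase and for
#'   fine-tuning).
#' @param batch minibatch size.
#' @param lr learning rate (constant).
#' @param momentum classical momentum coefficient.
#' @param seed integer seed.
#' @return List of class `sae_model`: `W`, `b` (6 layers, encoder then
#'   decoder), `layer_sizes`, `squash` (per-band affine map), `loss`
#'   (`pretrain` list of per-epoch paths, `finetune` per-epoch path).
#' @export
train_sae <- function(P, h = 13, hidden = c(300, 150), epochs = 40,
                      batch = 200, lr = 0.001, momentum = 0.9, seed = 1L) {
  if (inherits(P, "spectral_matrix")) P <- P$values
  P <- as.matrix(P)
  p <- ncol(P); n <- nrow(P)
  sizes <- c(p, hidden, h)
  if (any(diff(sizes) >= 0))
    stop("each layer must be smaller than the previous one (got ",
         paste(sizes, collapse = "-"), ")", call. = FALSE)
  squash <- squash_params(P)
  X <- apply_squash(P, squash)

  with_seed(seed, {
    n_enc <- length(sizes) - 1L
    encW <- vector("list", n_enc); encb <- vector("list", n_enc)
    decW <- vector("list", n_enc); decb <- vector("list", n_enc)
    pre_loss <- vector("list", n_enc)
    H <- X
    for (l in seq_len(n_enc)) {
      d_in <- sizes[l]; d_out <- sizes[l + 1L]
      W1 <- init_w(d_in, d_out); b1 <- init_b(d_out)
      W2 <- init_w(d_out, d_in); b2 <- init_b(d_in)
      ord <- shuffle_orders(nrow(H), epochs)
      fit <- mlp_train_sgd(H, H, list(W1, W2), list(b1, b2), epochs, batch,
                           lr, momentum, ord)
      encW[[l]] <- fit$W[[1]]; encb[[l]] <- fit$b[[1]]
      decW[[l]] <- fit$W[[2]]; decb[[l]] <- fit$b[[2]]
      pre_loss[[l]] <- fit$loss
      H <- sigmoid(H %*% encW[[l]] + rep(encb[[l]], each = nrow(H)))
    }
    W <- c(encW, rev(decW)); b <- c(encb, rev(decb))
    ord <- shuffle_orders(n, epochs)
    fit <- mlp_train_sgd(X, X, W, b, epochs, batch, lr, momentum, ord)
    structure(list(W = fit$W, b = fit$b,
                   layer_sizes = c(sizes, rev(sizes)[-1]),
                   h = h, squash = squash,
                   loss = list(pretrain = pre_loss, finetune = fit$loss)),
              class = "sae_model")
  })
}

#' Encode spectra with a trained stacked auto-encoder
#'
#' Forward pass through the encoder half only; rows map independently.
#' The training-time per-band squash is replayed before encoding.
#'
#' @param model an `sae_model` from [train_sae()].
#' @param m a [spectral_matrix()] or numeric matrix whose band count
#'   equals the model's input size.
#' @return Numeric matrix, n x h, entries in (0, 1).
#' @export
sae_encode <- function(model, m) {
  stopifnot(inherits(model, "sae_model"))
  if (inherits(m, "spectral_matrix")) m <- m$values
  m <- as.matrix(m)
  p <- model$layer_sizes[1]
  if (ncol(m) != p)
    stop("input has ", ncol(m), " bands; model expects ", p, call. = FALSE)
  A <- apply_squash(m, model$squash)
  n_enc <- (length(model$W)) / 2
  for (l in seq_len(n_enc))
    A <- sigmoid(A %*% model$W[[l]] + rep(model$b[[l]], each = nrow(A)))
  A
}

#' Reconstruct spectra with a trained stacked auto-encoder
#'
#' Full forward pass (encoder + decoder), with the stored squash inverted
#' at the output so reconstructions live on the input scale.
#'
#' @inheritParams sae_encode
#' @return Numeric matrix of reconstructed spectra on the input scale.
#' @export
sae_reconstruct <- function(model, m) {
  stopifnot(inherits(model, "sae_model"))
  if (inherits(m, "spectral_matrix")) m <- m$values
  A <- apply_squash(as.matrix(m), model$squash)
  for (l in seq_along(model$W))
    A <- sigmoid(A %*% model$W[[l]] + rep(model$b[[l]], each = nrow(A)))
  invert_squash(A, model$squash)
}

# per-band affine map onto [0.05, 0.95]
squash_params <- function(P) {
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  flat <- hi - lo < 1e-12
  hi[flat] <- lo[flat] + 1
  list(lo = lo, hi = hi)
}

apply_squash <- function(X, s) {
  0.05 + 0.9 * sweep(sweep(X, 2, s$lo), 2, s$hi - s$lo, "/")
}

invert_squash <- function(X, s) {
  sweep(sweep((X - 0.05) / 0.9, 2, s$hi - s$lo, "*"), 2, s$lo, "+")
}

init_w <- function(d_in, d_out) {
  s <- 1 / sqrt(d_in)   # uniform scaled by layer fan-in
  matrix(stats::runif(d_in * d_out, -s, s), d_in, d_out)
}

init_b <- function(d_out) numeric(d_out)

shuffle_orders <- function(n, epochs) {
  m <- matrix(0L, epochs, n)
  for (e in seq_len(epochs)) m[e, ] <- sample.int(n)
  m
}
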