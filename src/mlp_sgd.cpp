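// Minibatch SGD (with momentum) for a fully sigmoid multilayer
// perceptron under mean-squared reconstruction loss. Used for both the
// greedy layer-wise auto-encoder pretraining and the end-to-end
// fine-tuning of the stacked auto-encoder. Deterministic: the epoch-wise
// row orders are generated in R and passed in, and execution is
// single-threaded.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat sigm(const arma::mat& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// X: n x d_in inputs; Y: n x d_out targets; W, b: initial layer weights
// (list of d_{l-1} x d_l matrices) and offsets (list of row vectors);
// order: epochs x n matrix of 1-based row orders, one shuffled
// permutation per epoch. Returns trained W, b and the per-epoch mean
// squared reconstruction error (per element).
// [[Rcpp::export]]
List mlp_train_sgd(const arma::mat& X, const arma::mat& Y, List W_init,
                   List b_init, int epochs, int batch_size, double lr,
                   double momentum, const arma::imat& order) {
  const int n = X.n_rows;
  const int L = W_init.size();
  std::vector<arma::mat> W(L), vW(L);
  std::vector<arma::rowvec> b(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(W_init[l]);
    b[l] = as<arma::rowvec>(b_init[l]);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    vb[l].zeros(b[l].n_elem);
  }
  arma::vec loss(epochs, arma::fill::zeros);
  std::vector<arma::mat> A(L + 1);

  for (int e = 0; e < epochs; ++e) {
    double sse = 0.0;
    long cnt = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n) - 1;
      const int B = stop - start + 1;
      arma::uvec idx(B);
      for (int i = 0; i < B; ++i) idx[i] = order(e, start + i) - 1;
      A[0] = X.rows(idx);
      for (int l = 0; l < L; ++l)
        A[l + 1] = sigm(A[l] * W[l] + arma::repmat(b[l], B, 1));
      const arma::mat& out = A[L];
      arma::mat Yb = Y.rows(idx);
      arma::mat diff = out - Yb;
      sse += arma::accu(arma::square(diff));
      cnt += (long)B * Yb.n_cols;
      // backprop: dL/dz for MSE averaged over the batch
      arma::mat delta = (2.0 / B) * diff % out % (1.0 - out);
      for (int l = L - 1; l >= 0; --l) {
        arma::mat gW = A[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0)
          delta = (delta * W[l].t()) % A[l] % (1.0 - A[l]);
        vW[l] = momentum * vW[l] - lr * gW;
        vb[l] = momentum * vb[l] - lr * gb;
        W[l] += vW[l];
        b[l] += vb[l];
      }
    }
    loss[e] = sse / cnt;
  }
  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = NumericVector(b[l].begin(), b[l].end());
  }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["loss"] = NumericVector(loss.begin(), loss.end()));
}
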