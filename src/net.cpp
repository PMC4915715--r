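// Sigmoid feed-forward core: forward pass, exact backprop for the
// squared-error + L1 objective, and the per-sample SGD loop
//   w(t+1) = w(t) - eta * dE/dw + alpha * (w(t) - w(t-1)) + noise
// with eta = eta0 * decay^epoch and noise ~ N(0, (noise_coeff*sqrt(2*eta))^2).
// All randomness (shuffling, noise) goes through R's RNG so set.seed()
// governs reproducibility end to end.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::vec;

static std::vector<mat> list_to_mats(const List& L) {
  std::vector<mat> out(L.size());
  for (R_xlen_t i = 0; i < L.size(); ++i) out[i] = as<mat>(L[i]);
  return out;
}

static std::vector<vec> list_to_vecs(const List& L) {
  std::vector<vec> out(L.size());
  for (R_xlen_t i = 0; i < L.size(); ++i) out[i] = as<vec>(L[i]);
  return out;
}

static inline mat sigm(const mat& a) { return 1.0 / (1.0 + arma::exp(-a)); }

// Activations for one sample; act[0] is the raw input (no activation on the
// input layer), act[l] the sigmoid output of layer l.
static std::vector<vec> forward_one(const std::vector<mat>& W,
                                    const std::vector<vec>& b,
                                    const vec& x) {
  std::vector<vec> act(W.size() + 1);
  act[0] = x;
  for (size_t l = 0; l < W.size(); ++l)
    act[l + 1] = sigm(W[l] * act[l] + b[l]);
  return act;
}

// [[Rcpp::export]]
List cpp_forward(List W_, List b_, arma::vec x) {
  std::vector<mat> W = list_to_mats(W_);
  std::vector<vec> b = list_to_vecs(b_);
  std::vector<vec> act = forward_one(W, b, x);
  List out(act.size());
  for (size_t i = 0; i < act.size(); ++i) out[i] = act[i];
  return out;
}

// Batch forward: X has samples in rows; returns output-layer matrix.
// [[Rcpp::export]]
arma::mat cpp_forward_batch(List W_, List b_, arma::mat X) {
  std::vector<mat> W = list_to_mats(W_);
  std::vector<vec> b = list_to_vecs(b_);
  mat A = X.t();
  for (size_t l = 0; l < W.size(); ++l) {
    A = W[l] * A;
    A.each_col() += b[l];
    A = sigm(A);
  }
  return A.t();
}

// Gradients of E_n = sum_m (y_m - t_m)^2 + lambda * sum |w| (biases included,
// subgradient of |.| at 0 taken as 0) for a single (x, target) pair.
static void backprop_one(const std::vector<mat>& W, const std::vector<vec>& b,
                         const vec& x, const vec& target, double lambda,
                         std::vector<mat>& gW, std::vector<vec>& gb) {
  const size_t L = W.size();
  std::vector<vec> act = forward_one(W, b, x);
  // delta = dE/d(pre-activation); sigmoid' = y (1 - y)
  vec delta = 2.0 * (act[L] - target) % act[L] % (1.0 - act[L]);
  for (size_t l = L; l-- > 0;) {
    gW[l] = delta * act[l].t();
    gb[l] = delta;
    if (lambda > 0) {
      gW[l] += lambda * arma::sign(W[l]);
      gb[l] += lambda * arma::sign(b[l]);
    }
    if (l > 0)
      delta = (W[l].t() * delta) % act[l] % (1.0 - act[l]);
  }
}

// [[Rcpp::export]]
List cpp_backprop(List W_, List b_, arma::vec x, arma::vec target,
                  double lambda) {
  std::vector<mat> W = list_to_mats(W_);
  std::vector<vec> b = list_to_vecs(b_);
  std::vector<mat> gW(W.size());
  std::vector<vec> gb(W.size());
  backprop_one(W, b, x, target, lambda, gW, gb);
  List oW(W.size()), ob(W.size());
  for (size_t l = 0; l < W.size(); ++l) { oW[l] = gW[l]; ob[l] = gb[l]; }
  return List::create(_["W"] = oW, _["b"] = ob);
}

// Per-sample SGD with momentum on the realized step, L1 subgradient, and
// (optional) Gaussian noise injected into every weight and bias update.
// X, Y: samples in rows (Y = X for autoencoder training).
// epoch_offset shifts the learning-rate schedule (used when fine-tuning is
// meant to continue a decayed schedule instead of restarting it).
// Returns updated parameters and a per-epoch loss log: mean squared-error
// term over the epoch's updates plus the L1 penalty at epoch end.
// [[Rcpp::export]]
List cpp_train(List W_, List b_, arma::mat X, arma::mat Y,
               double eta0, double decay, double lambda, double alpha,
               double noise_coeff, int epochs, int epoch_offset,
               bool noise, bool shuffle) {
  std::vector<mat> W = list_to_mats(W_);
  std::vector<vec> b = list_to_vecs(b_);
  const size_t L = W.size();
  const arma::uword N = X.n_rows;

  std::vector<mat> gW(L), dW(L), pW(L);
  std::vector<vec> gb(L), db(L), pb(L);
  for (size_t l = 0; l < L; ++l) {
    pW[l].zeros(W[l].n_rows, W[l].n_cols);
    pb[l].zeros(b[l].n_elem);
  }

  NumericVector loss_log(epochs);
  std::vector<arma::uword> ord(N);
  for (arma::uword i = 0; i < N; ++i) ord[i] = i;

  for (int e = 0; e < epochs; ++e) {
    const double eta = eta0 * std::pow(decay, epoch_offset + e);
    const double sd = noise ? noise_coeff * std::sqrt(2.0 * eta) : 0.0;

    if (shuffle) {  // Fisher-Yates on R's RNG
      for (arma::uword i = N - 1; i > 0; --i) {
        arma::uword j = static_cast<arma::uword>(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(ord[i], ord[j]);
      }
    }

    double se_sum = 0.0;
    for (arma::uword s = 0; s < N; ++s) {
      const vec x = X.row(ord[s]).t();
      const vec t = Y.row(ord[s]).t();
      std::vector<vec> act = forward_one(W, b, x);
      se_sum += arma::accu(arma::square(act[L] - t));

      vec delta = 2.0 * (act[L] - t) % act[L] % (1.0 - act[L]);
      for (size_t l = L; l-- > 0;) {
        gW[l] = delta * act[l].t();
        gb[l] = delta;
        if (lambda > 0) {
          gW[l] += lambda * arma::sign(W[l]);
          gb[l] += lambda * arma::sign(b[l]);
        }
        if (l > 0)
          delta = (W[l].t() * delta) % act[l] % (1.0 - act[l]);
      }

      for (size_t l = 0; l < L; ++l) {
        dW[l] = -eta * gW[l] + alpha * pW[l];
        db[l] = -eta * gb[l] + alpha * pb[l];
        if (sd > 0.0) {
          for (arma::uword k = 0; k < dW[l].n_elem; ++k)
            dW[l](k) += sd * norm_rand();
          for (arma::uword k = 0; k < db[l].n_elem; ++k)
            db[l](k) += sd * norm_rand();
        }
        W[l] += dW[l];
        b[l] += db[l];
        pW[l] = dW[l];
        pb[l] = db[l];
      }
    }

    double pen = 0.0;
    if (lambda > 0)
      for (size_t l = 0; l < L; ++l)
        pen += arma::accu(arma::abs(W[l])) + arma::accu(arma::abs(b[l]));
    loss_log[e] = se_sum / static_cast<double>(N) + lambda * pen;
  }

  List oW(L), ob(L);
  for (size_t l = 0; l < L; ++l) { oW[l] = W[l]; ob[l] = b[l]; }
  return List::create(_["W"] = oW, _["b"] = ob, _["loss"] = loss_log);
}
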