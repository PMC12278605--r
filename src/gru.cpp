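// Compiled GRU kernels: batched forward pass, exact BPTT gradients of the
// mean binary cross-entropy, and the mini-batch training loop. The R-level
// implementation of the same equations (R/gru.R) is retained as the
// reference the test suite checks these kernels against.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct GruPars {
  arma::mat W_xr, W_xz, W_xh, W_hr, W_hz, W_hh;
  arma::rowvec b_r, b_z, b_h;
  arma::vec W_out;
  double b_out;
};

GruPars from_list(const List& p) {
  GruPars g;
  g.W_xr = as<arma::mat>(p["W_xr"]);
  g.W_xz = as<arma::mat>(p["W_xz"]);
  g.W_xh = as<arma::mat>(p["W_xh"]);
  g.W_hr = as<arma::mat>(p["W_hr"]);
  g.W_hz = as<arma::mat>(p["W_hz"]);
  g.W_hh = as<arma::mat>(p["W_hh"]);
  g.b_r = arma::rowvec(as<arma::vec>(p["b_r"]).t());
  g.b_z = arma::rowvec(as<arma::vec>(p["b_z"]).t());
  g.b_h = arma::rowvec(as<arma::vec>(p["b_h"]).t());
  g.W_out = as<arma::vec>(p["W_out"]);
  g.b_out = as<double>(p["b_out"]);
  return g;
}

List to_list(const GruPars& g) {
  return List::create(
      _["W_xr"] = g.W_xr, _["W_xz"] = g.W_xz, _["W_xh"] = g.W_xh,
      _["W_hr"] = g.W_hr, _["W_hz"] = g.W_hz, _["W_hh"] = g.W_hh,
      _["b_r"] = arma::vec(g.b_r.t()), _["b_z"] = arma::vec(g.b_z.t()),
      _["b_h"] = arma::vec(g.b_h.t()),
      _["W_out"] = arma::mat(g.W_out), _["b_out"] = g.b_out);
}

inline arma::mat sigm(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct Cache {
  std::vector<arma::mat> Hprev, R, Z, RH, Hb;
};

// forward over T steps; X is n x (T*d) with step t in cols [t*d, (t+1)*d)
arma::vec forward(const GruPars& g, const arma::mat& X, int T, int d,
                  Cache* cache, arma::mat* H_last) {
  const arma::uword n = X.n_rows;
  const arma::uword h = g.W_hr.n_rows;
  arma::mat H(n, h, arma::fill::zeros);
  if (cache) {
    cache->Hprev.resize(T); cache->R.resize(T); cache->Z.resize(T);
    cache->RH.resize(T); cache->Hb.resize(T);
  }
  for (int t = 0; t < T; ++t) {
    arma::mat Xt = X.cols(t * d, (t + 1) * d - 1);
    arma::mat R = sigm(Xt * g.W_xr + H * g.W_hr +
                       arma::repmat(g.b_r, n, 1));
    arma::mat Z = sigm(Xt * g.W_xz + H * g.W_hz +
                       arma::repmat(g.b_z, n, 1));
    arma::mat RH = R % H;
    arma::mat Hb = arma::tanh(Xt * g.W_xh + RH * g.W_hh +
                              arma::repmat(g.b_h, n, 1));
    arma::mat Hnew = (1.0 - Z) % H + Z % Hb;
    if (!Hnew.is_finite())
      stop("non-finite hidden state at time step %d", t + 1);
    if (cache) {
      cache->Hprev[t] = H; cache->R[t] = R; cache->Z[t] = Z;
      cache->RH[t] = RH; cache->Hb[t] = Hb;
    }
    H = Hnew;
  }
  if (H_last) *H_last = H;
  return sigm(H * g.W_out + g.b_out);
}

// gradients of mean BCE over this batch; returns squared global norm
double backward(const GruPars& g, const arma::mat& X, const arma::vec& y,
                int T, int d, const Cache& cache, const arma::mat& H_last,
                const arma::vec& p, GruPars& grad) {
  const arma::uword n = X.n_rows;
  grad.W_xr.zeros(arma::size(g.W_xr)); grad.W_xz.zeros(arma::size(g.W_xz));
  grad.W_xh.zeros(arma::size(g.W_xh)); grad.W_hr.zeros(arma::size(g.W_hr));
  grad.W_hz.zeros(arma::size(g.W_hz)); grad.W_hh.zeros(arma::size(g.W_hh));
  grad.b_r.zeros(arma::size(g.b_r)); grad.b_z.zeros(arma::size(g.b_z));
  grad.b_h.zeros(arma::size(g.b_h));
  arma::vec dlogit = (p - y) / static_cast<double>(n);
  grad.W_out = H_last.t() * dlogit;
  grad.b_out = arma::accu(dlogit);
  arma::mat dH = dlogit * g.W_out.t();
  for (int t = T - 1; t >= 0; --t) {
    const arma::mat& Hprev = cache.Hprev[t];
    const arma::mat& R = cache.R[t];
    const arma::mat& Z = cache.Z[t];
    const arma::mat& Hb = cache.Hb[t];
    arma::mat Xt = X.cols(t * d, (t + 1) * d - 1);
    arma::mat dZ = dH % (Hb - Hprev);
    arma::mat dAh = (dH % Z) % (1.0 - Hb % Hb);
    arma::mat dRH = dAh * g.W_hh.t();
    arma::mat dAr = (dRH % Hprev) % R % (1.0 - R);
    arma::mat dAz = dZ % Z % (1.0 - Z);
    grad.W_xh += Xt.t() * dAh;
    grad.W_hh += cache.RH[t].t() * dAh;
    grad.b_h += arma::sum(dAh, 0);
    grad.W_xr += Xt.t() * dAr;
    grad.W_hr += Hprev.t() * dAr;
    grad.b_r += arma::sum(dAr, 0);
    grad.W_xz += Xt.t() * dAz;
    grad.W_hz += Hprev.t() * dAz;
    grad.b_z += arma::sum(dAz, 0);
    dH = dH % (1.0 - Z) + dRH % R + dAr * g.W_hr.t() + dAz * g.W_hz.t();
  }
  double sq = arma::accu(arma::square(grad.W_xr)) +
              arma::accu(arma::square(grad.W_xz)) +
              arma::accu(arma::square(grad.W_xh)) +
              arma::accu(arma::square(grad.W_hr)) +
              arma::accu(arma::square(grad.W_hz)) +
              arma::accu(arma::square(grad.W_hh)) +
              arma::accu(arma::square(grad.b_r)) +
              arma::accu(arma::square(grad.b_z)) +
              arma::accu(arma::square(grad.b_h)) +
              arma::accu(arma::square(grad.W_out)) +
              grad.b_out * grad.b_out;
  return sq;
}

inline double bce(const arma::vec& p, const arma::vec& y) {
  const double eps = 1e-12;
  return -arma::mean(y % arma::log(arma::clamp(p, eps, 1.0)) +
                     (1.0 - y) % arma::log(arma::clamp(1.0 - p, eps, 1.0)));
}

}  // namespace

// [[Rcpp::export]]
arma::vec gru_predict_cpp(List params, arma::mat X, int T, int d) {
  GruPars g = from_list(params);
  return forward(g, X, T, d, nullptr, nullptr);
}

// [[Rcpp::export]]
List gru_grad_cpp(List params, arma::mat X, arma::vec y, int T, int d) {
  GruPars g = from_list(params);
  Cache cache;
  arma::mat H_last;
  arma::vec p = forward(g, X, T, d, &cache, &H_last);
  GruPars grad;
  backward(g, X, y, T, d, cache, H_last, p, grad);
  return to_list(grad);
}

// Mini-batch gradient-descent training. `perms` is an epochs x n matrix of
// 1-based shuffled indices precomputed in R so that shuffling semantics (and
// seed determinism) are owned by the R layer.
// [[Rcpp::export]]
List gru_train_cpp(List params, arma::mat X, arma::vec y, int T, int d,
                   double lr, IntegerMatrix perms, int batch,
                   double clip_norm) {
  GruPars g = from_list(params);
  const int epochs = perms.nrow();
  const int n = X.n_rows;
  arma::vec losses(epochs, arma::fill::zeros);
  int clipped = 0;
  Cache cache;
  GruPars grad;
  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    for (int s = 0; s < n; s += batch) {
      const int bn = std::min(batch, n - s);
      arma::uvec idx(bn);
      for (int k = 0; k < bn; ++k) idx[k] = perms(ep, s + k) - 1;
      arma::mat Xb = X.rows(idx);
      arma::vec yb = y.elem(idx);
      arma::mat H_last;
      arma::vec p = forward(g, Xb, T, d, &cache, &H_last);
      ep_loss += bce(p, yb) * bn;
      if (lr == 0.0) continue;
      double sq = backward(g, Xb, yb, T, d, cache, H_last, p, grad);
      double scale = 1.0;
      if (std::sqrt(sq) > clip_norm) {
        ++clipped;
        scale = clip_norm / std::sqrt(sq);
      }
      const double step = lr * scale;
      g.W_xr -= step * grad.W_xr; g.W_xz -= step * grad.W_xz;
      g.W_xh -= step * grad.W_xh; g.W_hr -= step * grad.W_hr;
      g.W_hz -= step * grad.W_hz; g.W_hh -= step * grad.W_hh;
      g.b_r -= step * grad.b_r; g.b_z -= step * grad.b_z;
      g.b_h -= step * grad.b_h;
      g.W_out -= step * grad.W_out; g.b_out -= step * grad.b_out;
    }
    losses[ep] = ep_loss / n;
  }
  return List::create(_["params"] = to_list(g), _["loss"] = losses,
                      _["clipped"] = clipped);
}
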