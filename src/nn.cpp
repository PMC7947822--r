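// Dense feed-forward network with elastic-net-penalized cost, trained by
// Adam with minibatches. Hidden layers use ReLU; the output head is softmax
// (classification, categorical cross-entropy) or linear (parameter
// prediction, per-observation residual sum of squares). Biases are one per
// destination unit (optionally one shared scalar per layer) and are never
// penalized. Arithmetic is single precision, matching the fp32 convention of
// mainstream deep-learning backends.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#define CLOUDR_SET_FTZ() do { \
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON); \
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON); } while (0)
#else
#define CLOUDR_SET_FTZ() do {} while (0)
#endif

using arma::fmat;
using arma::frowvec;

namespace {

struct Net {
  std::vector<fmat> W;
  std::vector<frowvec> b;
};

Net netFromR(const Rcpp::List& Wlist, const Rcpp::List& blist) {
  Net net;
  for (int l = 0; l < Wlist.size(); ++l) {
    net.W.push_back(arma::conv_to<fmat>::from(
        Rcpp::as<arma::mat>(Wlist[l])));
    net.b.push_back(arma::conv_to<frowvec>::from(
        Rcpp::as<arma::rowvec>(blist[l])));
  }
  return net;
}

// Forward pass; optionally keeps pre/post-activation caches for backprop.
fmat forwardPass(const Net& net, const fmat& X, int task,
                 std::vector<fmat>* acts = nullptr) {
  const int nlayer = static_cast<int>(net.W.size());
  fmat A = X;
  if (acts) { acts->clear(); acts->push_back(A); }
  for (int l = 0; l < nlayer; ++l) {
    fmat Z = A * net.W[l];
    Z.each_row() += net.b[l];
    if (l < nlayer - 1) {
      A = arma::clamp(Z, 0.0f, std::numeric_limits<float>::max());  // ReLU
      if (acts) acts->push_back(A);
    } else {
      A = Z;
    }
  }
  if (task == 0) {  // softmax rows
    arma::fvec mx = arma::max(A, 1);
    A.each_col() -= mx;
    A = arma::exp(A);
    arma::fvec rs = arma::sum(A, 1);
    A.each_col() /= rs;
  }
  return A;
}

double batchLoss(const fmat& Yhat, const fmat& Y, int task) {
  if (task == 0) {
    fmat p = arma::clamp(Yhat, 1e-12f, 1.0f);
    return -arma::accu(Y % arma::log(p)) / Yhat.n_rows;
  }
  fmat r = Yhat - Y;
  return arma::accu(r % r) / Yhat.n_rows;
}

double penaltyValue(const Net& net, double lambda, double gamma) {
  double pen = 0.0;
  for (const fmat& W : net.W)
    pen += (1.0 - gamma) * arma::accu(arma::square(W)) +
           gamma * arma::accu(arma::abs(W));
  return lambda * pen;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_nn_forward(Rcpp::List Wlist, Rcpp::List blist,
                                   Rcpp::NumericMatrix X, int task) {
  Net net = netFromR(Wlist, blist);
  fmat Xf = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(X));
  fmat out = forwardPass(net, Xf, task);
  return Rcpp::wrap(arma::conv_to<arma::mat>::from(out));
}

// [[Rcpp::export]]
Rcpp::List cpp_nn_train(Rcpp::NumericMatrix X, Rcpp::NumericMatrix Y,
                        Rcpp::List Wlist, Rcpp::List blist, int task,
                        double lambda, double gamma, double lr, double beta1,
                        double beta2, double eps, int batchSize, int epochs,
                        int seed, bool scalarBias) {
  CLOUDR_SET_FTZ();  // subnormal floats flushed to zero (Adam second
                     // moments of vanishing gradients otherwise stall SSE)
  Net net = netFromR(Wlist, blist);
  const int nlayer = static_cast<int>(net.W.size());
  const arma::uword N = X.nrow();
  fmat Xf = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(X));
  fmat Yf = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(Y));

  std::vector<fmat> mW(nlayer), vW(nlayer);
  std::vector<frowvec> mb(nlayer), vb(nlayer);
  for (int l = 0; l < nlayer; ++l) {
    mW[l].zeros(arma::size(net.W[l]));
    vW[l].zeros(arma::size(net.W[l]));
    mb[l].zeros(net.b[l].n_elem);
    vb[l].zeros(net.b[l].n_elem);
  }

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<arma::uword> order(N);
  for (arma::uword i = 0; i < N; ++i) order[i] = i;

  const float flr = static_cast<float>(lr);
  const float fb1 = static_cast<float>(beta1);
  const float fb2 = static_cast<float>(beta2);
  const float feps = static_cast<float>(eps);
  const float l2c = static_cast<float>(2.0 * lambda * (1.0 - gamma));
  const float l1c = static_cast<float>(lambda * gamma);

  std::vector<double> costHistory;
  costHistory.reserve(epochs);
  long step = 0;
  std::vector<fmat> acts;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double epochLoss = 0.0;
    for (arma::uword start = 0; start < N; start += batchSize) {
      arma::uword stop = std::min<arma::uword>(start + batchSize, N) - 1;
      arma::uvec idx(stop - start + 1);
      for (arma::uword i = 0; i < idx.n_elem; ++i) idx[i] = order[start + i];
      fmat Xb = Xf.rows(idx);
      fmat Yb = Yf.rows(idx);
      const float nb = static_cast<float>(Xb.n_rows);

      fmat Yhat = forwardPass(net, Xb, task, &acts);
      epochLoss += batchLoss(Yhat, Yb, task) * Xb.n_rows;
      if (!Yhat.is_finite())
        Rcpp::stop("non-finite network output during training (epoch %d)",
                   ep + 1);

      // Output-layer gradient of the mean batch loss w.r.t. logits.
      fmat delta = (Yhat - Yb) / nb;
      if (task != 0) delta *= 2.0f;
      ++step;
      const float c1 = 1.0f - std::pow(fb1, static_cast<float>(step));
      const float c2 = 1.0f - std::pow(fb2, static_cast<float>(step));
      for (int l = nlayer - 1; l >= 0; --l) {
        fmat gW = acts[l].t() * delta;
        gW += l2c * net.W[l];
        if (l1c > 0.0f) gW += l1c * arma::sign(net.W[l]);
        frowvec gb = arma::sum(delta, 0);
        if (scalarBias) gb.fill(arma::accu(gb));
        if (l > 0) {
          delta = delta * net.W[l].t();
          delta %= arma::conv_to<fmat>::from(acts[l] > 0.0f);  // ReLU mask
        }
        mW[l] = fb1 * mW[l] + (1.0f - fb1) * gW;
        vW[l] = fb2 * vW[l] + (1.0f - fb2) * arma::square(gW);
        net.W[l] -= flr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + feps);
        mb[l] = fb1 * mb[l] + (1.0f - fb1) * gb;
        vb[l] = fb2 * vb[l] + (1.0f - fb2) * arma::square(gb);
        net.b[l] -= flr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + feps);
      }
    }
    costHistory.push_back(epochLoss / N +
                          penaltyValue(net, lambda, gamma));
    if ((ep & 15) == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::List Wout(nlayer), bout(nlayer);
  for (int l = 0; l < nlayer; ++l) {
    Wout[l] = Rcpp::wrap(arma::conv_to<arma::mat>::from(net.W[l]));
    bout[l] = Rcpp::wrap(arma::conv_to<arma::rowvec>::from(net.b[l]));
  }
  return Rcpp::List::create(Rcpp::Named("weights") = Wout,
                            Rcpp::Named("biases") = bout,
                            Rcpp::Named("costHistory") = costHistory);
}
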