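#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Deterministic, platform-independent PRNG (splitmix64). The training loop
// must not touch R's global RNG: every model draws its own stream from an
// explicit seed so per-target runs can be replayed in isolation.
static inline uint64_t splitmix64_next(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline double rng_unif(uint64_t &state) {
  // 53-bit mantissa draw in [0, 1)
  return (splitmix64_next(state) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid_act(double v, double a) {
  return 1.0 / (1.0 + std::exp(-a * v));
}

// One 3-layer perceptron (n_inputs - n_hidden - 1), online backpropagation
// with momentum, trained on (Xtr, dtr); (Xmon, dmon) is only evaluated for
// the per-epoch MSE that drives early stopping.
//
// Stopping: epoch MSE below mse_threshold, or no improvement of more than
// improve_tol over the best MSE for mse_window consecutive epochs.
//
// Weight layout: w_ih is (n_inputs + 1) x n_hidden with the bias in row 0
// (column-major, matching the R matrix); w_ho has the bias first.
// [[Rcpp::export]]
List cpp_train_mlp(NumericMatrix Xtr, NumericVector dtr,
                   NumericMatrix Xmon, NumericVector dmon,
                   int n_hidden, int epochs,
                   double learning_rate, double momentum, double slope,
                   double mse_threshold, int mse_window, double improve_tol,
                   double w_lo, double w_hi, double seed) {
  const int ntr = Xtr.nrow(), ni = Xtr.ncol();
  const int nmon = Xmon.nrow();
  if (dtr.size() != ntr) stop("length of training target does not match rows");
  if (dmon.size() != nmon) stop("length of monitor target does not match rows");
  if (nmon == 0) stop("monitor set must not be empty");

  uint64_t rng = (uint64_t)((int64_t)seed) ^ 0x5DEECE66DULL;
  // burn one draw so seed 0 does not start the stream at state 0
  splitmix64_next(rng);

  const int nwih = (ni + 1) * n_hidden;
  std::vector<double> w_ih(nwih), w_ho(n_hidden + 1);
  std::vector<double> dw_ih(nwih, 0.0), dw_ho(n_hidden + 1, 0.0);
  for (int k = 0; k < nwih; ++k) w_ih[k] = w_lo + rng_unif(rng) * (w_hi - w_lo);
  for (int h = 0; h <= n_hidden; ++h) w_ho[h] = w_lo + rng_unif(rng) * (w_hi - w_lo);

  // row-major copies for cache-friendly per-sample access
  std::vector<double> xtr((size_t)ntr * ni), xmon((size_t)nmon * ni);
  for (int s = 0; s < ntr; ++s)
    for (int i = 0; i < ni; ++i) xtr[(size_t)s * ni + i] = Xtr(s, i);
  for (int s = 0; s < nmon; ++s)
    for (int i = 0; i < ni; ++i) xmon[(size_t)s * ni + i] = Xmon(s, i);

  std::vector<int> order(ntr);
  for (int s = 0; s < ntr; ++s) order[s] = s;
  std::vector<double> hid(n_hidden), delta_h(n_hidden);
  std::vector<double> trace;
  trace.reserve(epochs);

  double best_mse = R_PosInf;
  int best_epoch = 0, epochs_run = 0;

  for (int ep = 1; ep <= epochs; ++ep) {
    // fresh sample order each epoch
    for (int s = ntr - 1; s > 0; --s) {
      int j = (int)(splitmix64_next(rng) % (uint64_t)(s + 1));
      std::swap(order[s], order[j]);
    }
    for (int si = 0; si < ntr; ++si) {
      const double *x = &xtr[(size_t)order[si] * ni];
      const double d = dtr[order[si]];
      // forward
      for (int h = 0; h < n_hidden; ++h) {
        const double *w = &w_ih[(size_t)h * (ni + 1)];
        double z = w[0];
        for (int i = 0; i < ni; ++i) z += w[i + 1] * x[i];
        hid[h] = sigmoid_act(z, slope);
      }
      double zo = w_ho[0];
      for (int h = 0; h < n_hidden; ++h) zo += w_ho[h + 1] * hid[h];
      const double y = sigmoid_act(zo, slope);
      if (y == d) continue;  // perfect match: no adjustment for this pattern
      // backpropagated error terms for sigmoid units (slope-aware)
      const double delta_o = (d - y) * slope * y * (1.0 - y);
      for (int h = 0; h < n_hidden; ++h)
        delta_h[h] = delta_o * w_ho[h + 1] * slope * hid[h] * (1.0 - hid[h]);
      // hidden -> output updates (bias input is 1)
      double dw = learning_rate * delta_o + momentum * dw_ho[0];
      dw_ho[0] = dw; w_ho[0] += dw;
      for (int h = 0; h < n_hidden; ++h) {
        dw = learning_rate * delta_o * hid[h] + momentum * dw_ho[h + 1];
        dw_ho[h + 1] = dw; w_ho[h + 1] += dw;
      }
      // input -> hidden updates
      for (int h = 0; h < n_hidden; ++h) {
        double *w = &w_ih[(size_t)h * (ni + 1)];
        double *pd = &dw_ih[(size_t)h * (ni + 1)];
        const double lrd = learning_rate * delta_h[h];
        dw = lrd + momentum * pd[0];
        pd[0] = dw; w[0] += dw;
        for (int i = 0; i < ni; ++i) {
          dw = lrd * x[i] + momentum * pd[i + 1];
          pd[i + 1] = dw; w[i + 1] += dw;
        }
      }
    }
    // monitored MSE for this epoch
    double sse = 0.0;
    for (int s = 0; s < nmon; ++s) {
      const double *x = &xmon[(size_t)s * ni];
      double zo = w_ho[0];
      for (int h = 0; h < n_hidden; ++h) {
        const double *w = &w_ih[(size_t)h * (ni + 1)];
        double z = w[0];
        for (int i = 0; i < ni; ++i) z += w[i + 1] * x[i];
        zo += w_ho[h + 1] * sigmoid_act(z, slope);
      }
      const double e = dmon[s] - sigmoid_act(zo, slope);
      sse += e * e;
    }
    const double mse = sse / nmon;
    trace.push_back(mse);
    epochs_run = ep;
    if (mse < best_mse - improve_tol) { best_mse = mse; best_epoch = ep; }
    if (mse < mse_threshold) break;
    if (ep - best_epoch >= mse_window) break;
  }

  NumericMatrix w_ih_out(ni + 1, n_hidden);
  for (int h = 0; h < n_hidden; ++h)
    for (int i = 0; i <= ni; ++i) w_ih_out(i, h) = w_ih[(size_t)h * (ni + 1) + i];
  NumericVector w_ho_out(n_hidden + 1);
  for (int h = 0; h <= n_hidden; ++h) w_ho_out[h] = w_ho[h];

  return List::create(_["w_ih"] = w_ih_out, _["w_ho"] = w_ho_out,
                      _["mse_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["epochs_run"] = epochs_run);
}
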