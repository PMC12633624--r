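// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Iterate x(t+1) = tanh(W x(t) + I(t)).  `inputs` is horizon x N (row t is
// the input applied at step t) or NULL.  Returns (horizon+1) x N states,
// initial state included.
// [[Rcpp::export]]
arma::mat cpp_simulate_rnn(const arma::mat& W, const arma::vec& x0,
                           Nullable<NumericMatrix> inputs, int horizon) {
  int n = x0.n_elem;
  arma::mat I;
  bool has_in = inputs.isNotNull();
  if (has_in) I = as<arma::mat>(inputs.get());
  arma::mat states(horizon + 1, n);
  arma::vec x = x0;
  states.row(0) = x.t();
  for (int t = 0; t < horizon; ++t) {
    arma::vec pre = W * x;
    if (has_in) pre += I.row(t).t();
    x = arma::tanh(pre);
    states.row(t + 1) = x.t();
    if ((t & 0xFF) == 0xFF) Rcpp::checkUserInterrupt();
  }
  return states;
}

// Benettin QR Lyapunov accumulation.  An orthonormal frame Q of m tangent
// vectors is pushed through the per-step Jacobian diag(1 - x(t+1)^2) W
// (just W when `linear`), re-orthonormalized by economy QR with the sign
// convention diag(R) > 0, and log R_ii accumulated after `warmup` steps.
// Per-step log contractions are clamped below at `floor_log` (the floored
// flag records whether the clamp fired), so zero maps return finite values.
// `keep_states` > 0 additionally returns the last keep_states states
// (nonlinear mode only).
// [[Rcpp::export]]
List cpp_lyapunov(const arma::mat& W, const arma::vec& x0, int horizon,
                  int warmup, int m, bool linear,
                  Nullable<NumericMatrix> inputs,
                  Nullable<NumericMatrix> frame0, double floor_log,
                  int keep_states) {
  int n = W.n_rows;
  arma::mat I;
  bool has_in = inputs.isNotNull();
  if (has_in) I = as<arma::mat>(inputs.get());
  arma::mat Q;
  if (frame0.isNotNull()) {
    Q = as<arma::mat>(frame0.get());
  } else {
    Q = arma::eye(n, m);
  }
  arma::vec x = x0;
  arma::vec cum(m, arma::fill::zeros);
  bool floored = false;
  arma::mat kept;
  int kfrom = horizon - keep_states, kcount = 0;
  if (keep_states > 0) kept.set_size(keep_states, n);

  for (int t = 0; t < horizon; ++t) {
    arma::vec d;
    if (!linear) {
      arma::vec pre = W * x;
      if (has_in) pre += I.row(t).t();
      x = arma::tanh(pre);
      if (!x.is_finite())
        stop("non-finite network state at step %d", t + 1);
      d = 1.0 - arma::square(x);
      if (keep_states > 0 && t >= kfrom) kept.row(kcount++) = x.t();
    }
    arma::mat Z = W * Q;
    if (!linear) Z.each_col() %= d;
    arma::mat Qn, R;
    if (!arma::qr_econ(Qn, R, Z))
      stop("QR decomposition failed at step %d", t + 1);
    for (int j = 0; j < m; ++j) {
      if (R(j, j) < 0) {
        Qn.col(j) *= -1.0;
        R.row(j) *= -1.0;
      }
    }
    if (t >= warmup) {
      for (int j = 0; j < m; ++j) {
        double lr = std::log(R(j, j));
        if (!(lr >= floor_log)) {  // catches -Inf and NaN
          lr = floor_log;
          floored = true;
        }
        cum[j] += lr;
      }
    }
    Q = Qn;
    if ((t & 0xFF) == 0xFF) Rcpp::checkUserInterrupt();
  }
  arma::vec lam = arma::sort(cum / (double)(horizon - warmup), "descend");
  List out = List::create(_["exponents"] = lam, _["floored"] = floored,
                          _["final_state"] = x);
  if (keep_states > 0) out["states"] = kept;
  return out;
}
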