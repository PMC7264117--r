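// Fast path for the training loop. Semantics are defined by the plain-R
// reference engine in run_training(); the two are cross-checked in the tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigmoid(double h, double slope, double threshold) {
  double z = -2.0 * slope * (h - threshold);
  if (z > 700.0) z = 700.0;
  if (z < -700.0) z = -700.0;
  return 1.0 / (1.0 + std::exp(z));
}

// [[Rcpp::export]]
List cpp_train_loop(arma::mat W, arma::mat mask, arma::vec h,
                    arma::vec eye_pref, arma::vec ret_pref,
                    double eye_peak, double eye_width,
                    double ret_peak, double ret_width,
                    double in_slope, double in_theta,
                    double out_slope, double out_theta, double sparseness,
                    double tau, double dt, double learning_rate,
                    arma::vec x, arma::vec y,
                    arma::ivec period, arma::ivec learn) {
  const arma::uword n_out = W.n_rows;
  const arma::uword n_eye = eye_pref.n_elem;
  const arma::uword n_ret = ret_pref.n_elem;
  const arma::uword n_in = n_eye + n_ret;
  const arma::uword n_steps = x.n_elem;
  if (W.n_cols != n_in) stop("weight matrix width does not match input layer");

  // afferent index lists: only masked synapses exist
  std::vector<arma::uvec> aff(n_out);
  double n_masked = 0.0;
  for (arma::uword i = 0; i < n_out; ++i) {
    aff[i] = arma::find(mask.row(i) > 0.5);
    n_masked += aff[i].n_elem;
  }

  const int n_periods = period.max();
  arma::vec sp_sum(n_periods, arma::fill::zeros);
  arma::vec dw_period(n_periods, arma::fill::zeros);
  arma::vec n_in_period(n_periods, arma::fill::zeros);

  // nearest-rank percentile index (1-based k-th smallest)
  arma::uword k = (arma::uword)std::ceil(sparseness / 100.0 * n_out);
  if (k < 1) k = 1;

  arma::vec v_in(n_in), v_out(n_out), h_sorted(n_out);
  const double lr_dt = dt * learning_rate;

  arma::mat W_period = W;   // weights at the start of the current period
  int current_period = n_steps > 0 ? period(0) : 1;

  for (arma::uword s = 0; s < n_steps; ++s) {
    if (period(s) != current_period) {
      // close out the finished period's weight-change log entry
      dw_period(current_period - 1) =
        arma::accu(arma::abs(W - W_period)) / n_masked;
      W_period = W;
      current_period = period(s);
    }

    // instantaneous input rates: eye units see y, retinal units see x
    for (arma::uword j = 0; j < n_eye; ++j) {
      double d = y(s) - eye_pref(j);
      v_in(j) = sigmoid(eye_peak * std::exp(-d * d / (2.0 * eye_width * eye_width)),
                        in_slope, in_theta);
    }
    for (arma::uword j = 0; j < n_ret; ++j) {
      double d = x(s) - ret_pref(j);
      v_in(n_eye + j) = sigmoid(ret_peak * std::exp(-d * d / (2.0 * ret_width * ret_width)),
                                in_slope, in_theta);
    }

    // leaky-integrator Forward-Euler step (masked synapses only)
    const double euler = dt / tau;
    for (arma::uword i = 0; i < n_out; ++i) {
      double drive = 0.0;
      const arma::uvec &ai = aff[i];
      for (arma::uword q = 0; q < ai.n_elem; ++q) drive += W(i, ai(q)) * v_in(ai(q));
      h(i) += euler * (-h(i) + drive);
    }
    if (!h.is_finite()) stop("non-finite output activation at step %d", (int)(s + 1));

    // percentile competition
    h_sorted = arma::sort(h);
    double p = h_sorted(k - 1);
    double frac_active = 0.0;
    for (arma::uword i = 0; i < n_out; ++i) {
      v_out(i) = sigmoid(h(i) - p, out_slope, out_theta);
      if (v_out(i) > 0.5) frac_active += 1.0;
    }
    int pd = period(s) - 1;
    sp_sum(pd) += frac_active / (double)n_out;
    n_in_period(pd) += 1.0;

    if (learn(s)) {
      for (arma::uword i = 0; i < n_out; ++i) {
        const arma::uvec &ai = aff[i];
        const double g = lr_dt * v_out(i);
        double ss = 0.0;
        for (arma::uword q = 0; q < ai.n_elem; ++q) {
          double w = W(i, ai(q)) + g * v_in(ai(q));
          W(i, ai(q)) = w;
          ss += w * w;
        }
        if (ss < 1e-24) stop("zero-norm weight row after update");
        const double inv = 1.0 / std::sqrt(ss);
        for (arma::uword q = 0; q < ai.n_elem; ++q) W(i, ai(q)) *= inv;
      }
    }
  }
  if (n_steps > 0) {
    dw_period(current_period - 1) =
      arma::accu(arma::abs(W - W_period)) / n_masked;
  }

  return List::create(
    _["weights"] = W, _["h"] = h,
    _["sparseness"] = sp_sum / n_in_period,
    _["mean_abs_dw"] = dw_period);
}
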