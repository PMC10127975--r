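#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Growth-law codes: 1 exponential, 2 logistic, 3 exponential-linear.
static inline double growth_rate_c(int law, double a, double K, double l0,
                                   double l1, double psi, double v) {
  switch (law) {
  case 1:
    return a * v;
  case 2:
    return a * v * (1.0 - v / K);
  default: {
    if (v <= 0.0) return 0.0;
    // bracket (1 + (l0 v / l1)^psi)^(-1/psi) evaluated in log space
    double lr = psi * (std::log(l0) + std::log(v) - std::log(l1));
    double lden = (lr > 0.0) ? (lr + std::log1p(std::exp(-lr))) / psi
                             : std::log1p(std::exp(lr)) / psi;
    return l0 * v * std::exp(-lden);
  }
  }
}

static inline double hhat(double t, double eps) {
  return 0.5 * (1.0 + std::tanh(t / eps));
}

// Sum over treatment windows of (H(t-tau)-H(t-tau-tw))/tw, truncated to
// windows within `cutoff` of t. tau is sorted ascending.
static inline double window_sum(double t, const double* tau, int ntau,
                                double tw, double eps, double cutoff,
                                bool hard) {
  double s = 0.0;
  for (int i = 0; i < ntau; ++i) {
    double dt = t - tau[i];
    if (dt < -cutoff) break;        // all later windows are further right
    if (dt > tw + cutoff) continue; // window already passed
    if (hard) {
      if (dt >= 0.0 && dt < tw) s += 1.0;
    } else {
      s += hhat(dt, eps) - hhat(dt - tw, eps);
    }
  }
  return s / tw;
}

struct TreatedRhs {
  int law;
  double a, K, l0, l1, psi;
  double kill; // 1 - exp(-alpha d - beta d^2)
  const double* tau;
  int ntau;
  double tw, eps, cutoff;
  bool hard;
  long n_evals;

  double operator()(double t, double v) {
    ++n_evals;
    double f = growth_rate_c(law, a, K, l0, l1, psi, v);
    if (kill != 0.0 && ntau > 0)
      f -= v * kill * window_sum(t, tau, ntau, tw, eps, cutoff, hard);
    return f;
  }
};

// Caputo Adams-Bashforth-Moulton predictor-corrector (Diethelm-Ford-Freed)
// for the treated tumour models. Fixed step h, n_steps steps from t = 0.
// At mu = 1 the weights collapse to the classical one-step AB (rectangle)
// predictor and AM (trapezoid) corrector, which admit O(N) running sums.
// [[Rcpp::export]]
List abm_solve_model_cpp(int law, double a, double K, double l0, double l1,
                         double psi, double alpha, double beta, double eps,
                         double dose, NumericVector tau, double tw,
                         double cutoff, bool hard, double v0, double mu,
                         double h, int n_steps, int corr_iters) {
  if (!(mu > 0.0 && mu <= 1.0)) stop("fractional order mu must lie in (0, 1]");
  if (h <= 0.0) stop("step size h must be > 0");
  if (corr_iters < 0) stop("corrector iteration count must be >= 0");

  TreatedRhs rhs{law, a, K, l0, l1, psi,
                 1.0 - std::exp(-alpha * dose - beta * dose * dose),
                 tau.begin(), (int)tau.size(), tw, eps, cutoff, hard, 0};

  int N = n_steps;
  NumericVector v(N + 1);
  std::vector<double> f(N + 1);
  v[0] = v0;
  f[0] = rhs(0.0, v0);
  bool negative = false;

  if (mu == 1.0) {
    // Running-sum reduction: predictor v0 + h*S, corrector trapezoid.
    double S = 0.0; // sum of f_0..f_n
    for (int n = 0; n < N; ++n) {
      S += f[n];
      double t1 = (n + 1) * h;
      double vp = v0 + h * S;
      double base = v0 + h * (S - 0.5 * f[0]);
      double vc = vp;
      for (int it = 0; it < corr_iters; ++it)
        vc = base + 0.5 * h * rhs(t1, vc);
      if (!std::isfinite(vc))
        stop("non-finite state at step %d (t = %g)", n + 1, t1);
      v[n + 1] = vc;
      f[n + 1] = rhs(t1, vc);
      if (vc < 0.0) negative = true;
    }
  } else {
    double g1 = std::tgamma(mu + 1.0); // Gamma(mu) * mu
    double g2 = std::tgamma(mu + 2.0); // Gamma(mu) * mu * (mu+1)
    double wp = std::pow(h, mu) / g1;  // predictor weight scale
    double wc = std::pow(h, mu) / g2;  // corrector weight scale
    // precomputed kernels: dp[k] = (k+1)^mu - k^mu,
    // d2q[k] = (k+2)^(mu+1) - 2(k+1)^(mu+1) + k^(mu+1)
    std::vector<double> p(N + 2), q(N + 2), dp(N + 1), d2q(N);
    for (int k = 0; k <= N + 1; ++k) {
      p[k] = std::pow((double)k, mu);
      q[k] = std::pow((double)k, mu + 1.0);
    }
    for (int k = 0; k <= N; ++k) dp[k] = p[k + 1] - p[k];
    for (int k = 0; k < N; ++k) d2q[k] = q[k + 2] - 2.0 * q[k + 1] + q[k];

    for (int n = 0; n < N; ++n) {
      double t1 = (n + 1) * h;
      // j = 0 terms, then a single fused pass over the history
      double sp = dp[n] * f[0];
      double sc = (q[n] - (n - mu) * p[n + 1]) * f[0];
      const double* fj = f.data();
      const double* dpk = dp.data();
      const double* d2qk = d2q.data();
      for (int j = 1; j <= n; ++j) {
        double fv = fj[j];
        sp += dpk[n - j] * fv;
        sc += d2qk[n - j] * fv;
      }
      double vp = v0 + wp * sp;
      double base = v0 + wc * sc;
      double vc = vp;
      for (int it = 0; it < corr_iters; ++it)
        vc = base + wc * rhs(t1, vc);
      if (!std::isfinite(vc))
        stop("non-finite state at step %d (t = %g)", n + 1, t1);
      v[n + 1] = vc;
      f[n + 1] = rhs(t1, vc);
      if (vc < 0.0) negative = true;
    }
  }

  return List::create(_["v"] = v, _["n_evals"] = (double)rhs.n_evals,
                      _["negative"] = negative);
}

// Vectorized treated right-hand side (used for fast trajectory diagnostics).
// [[Rcpp::export]]
NumericVector treated_rhs_cpp(int law, double a, double K, double l0,
                              double l1, double psi, double alpha, double beta,
                              double eps, double dose, NumericVector tau,
                              double tw, double cutoff, bool hard,
                              NumericVector t, NumericVector v) {
  TreatedRhs rhs{law, a, K, l0, l1, psi,
                 1.0 - std::exp(-alpha * dose - beta * dose * dose),
                 tau.begin(), (int)tau.size(), tw, eps, cutoff, hard, 0};
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rhs(t[i], v[i % v.size()]);
  return out;
}
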