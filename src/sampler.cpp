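#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Adaptive random-walk Metropolis-within-Gibbs for the censored hierarchical
// Poisson model. Blocks: intercept, each fixed-effect coefficient, each
// county random intercept, and the random-effect variance. Proposal scales
// adapt by Robbins-Monro toward 44% acceptance during burn-in only, so the
// retained draws come from a fixed (valid) kernel.
//
// The sampler works in "centered" coordinates: the caller centers covariate
// columns and passes the column means (xbar); the state intercept theta0
// equals mu + beta.xbar, and the prior on mu is evaluated through that
// identity. Draws are reported on the original (mu) scale.

static const double TARGET_ACC = 0.44;

struct RecLik {
  const int *y;            // exact count (ignored when censored)
  const int *cens;         // 1 = interval censored
  const double *lgam_y;    // lgamma(y+1) for exact records
  int lo, hi;              // censored interval (lo, hi]
  std::vector<double> lgam_int;  // lgamma(y+1) for y in lo+1..hi

  double operator()(int i, double lp) const {
    if (lp > 700.0) lp = 700.0;
    if (lp < -700.0) lp = -700.0;
    double lam = std::exp(lp);
    if (!cens[i])
      return y[i] * lp - lam - lgam_y[i];
    // log sum_{yy=lo+1}^{hi} exp(yy*lp - lam - lgamma(yy+1))
    double m = -HUGE_VAL;
    double t[64];
    int k = 0;
    for (int yy = lo + 1; yy <= hi; ++yy, ++k) {
      t[k] = yy * lp - lam - lgam_int[k];
      if (t[k] > m) m = t[k];
    }
    double s = 0.0;
    for (int j = 0; j < k; ++j) s += std::exp(t[j] - m);
    return m + std::log(s);
  }
};

static inline double dnorm_log(double x, double mean, double var) {
  double d = x - mean;
  return -0.5 * (std::log(2.0 * M_PI * var) + d * d / var);
}

// [[Rcpp::export(name = ".sampler_cpp")]]
List sampler_cpp(IntegerVector y, IntegerVector cens, NumericVector offset,
                 NumericMatrix X, IntegerVector county, int n_county,
                 int lo, int hi, NumericVector xbar,
                 double mu_mean, double mu_var,
                 NumericVector beta_mean, double beta_var, double s2_upper,
                 NumericVector init_theta, NumericVector init_b,
                 double init_s2, LogicalVector update_beta, bool update_s2,
                 NumericVector county_x, bool swap_moves,
                 int n_iter, int n_burn, int thin) {
  const int n = y.size();
  const int p = X.ncol();          // fixed-effect covariates (7)
  const int J = n_county;

  RecLik lik;
  std::vector<double> lgam_y(n);
  for (int i = 0; i < n; ++i)
    lgam_y[i] = cens[i] ? 0.0 : std::lgamma((double)y[i] + 1.0);
  lik.y = y.begin();
  lik.cens = cens.begin();
  lik.lgam_y = lgam_y.data();
  lik.lo = lo;
  lik.hi = hi;
  if (hi - lo > 64) stop("censoring interval wider than supported");
  for (int yy = lo + 1; yy <= hi; ++yy)
    lik.lgam_int.push_back(std::lgamma((double)yy + 1.0));

  // per-column nonzero record indices (dummy columns are sparse)
  std::vector< std::vector<int> > colidx(p);
  for (int k = 0; k < p; ++k)
    for (int i = 0; i < n; ++i)
      if (X(i, k) != 0.0) colidx[k].push_back(i);
  // county -> record indices
  std::vector< std::vector<int> > cidx(J);
  for (int i = 0; i < n; ++i) cidx[county[i]].push_back(i);

  // state
  double theta0 = init_theta[0];
  std::vector<double> beta(p);
  for (int k = 0; k < p; ++k) beta[k] = init_theta[k + 1];
  std::vector<double> b(init_b.begin(), init_b.end());
  double s2 = init_s2;

  std::vector<double> eta(n), ll(n), llprop(n);
  for (int i = 0; i < n; ++i) {
    double e = offset[i] + theta0;
    for (int k = 0; k < p; ++k) e += X(i, k) * beta[k];
    e += (J > 0) ? b[county[i]] : 0.0;
    eta[i] = e;
    ll[i] = lik(i, e);
    if (!R_finite(ll[i]))
      stop("non-finite likelihood at initialization (record %d)", i + 1);
  }

  // adaptive log proposal scales
  std::vector<double> ls_th(p + 1, std::log(0.1));
  std::vector<double> ls_b(J, std::log(0.5));
  double ls_s2 = std::log(0.5);
  std::vector<double> ls_sw(2, std::log(0.2));
  std::vector<long> nprop_th(p + 1, 0), nprop_b(J, 0), nprop_sw(2, 0);
  long nprop_s2 = 0;
  std::vector<double> acc_th(p + 1, 0.0), acc_b(J, 0.0);
  double acc_s2 = 0.0;
  long n_post = 0;

  auto adapt = [](double &ls, long &cnt, double alpha, bool adapting) {
    if (!adapting) return;
    ++cnt;
    double g = std::pow((double)cnt, -0.6);
    ls += g * (alpha - TARGET_ACC);
    if (ls > 5.0) ls = 5.0;
    if (ls < -12.0) ls = -12.0;
  };

  const int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_keep, 2 + p + J);
  int keep_row = 0;

  // prior for mu expressed through theta0 = mu + beta.xbar
  auto mu_from_state = [&](double th0, const std::vector<double> &be) {
    double m = th0;
    for (int k = 0; k < p; ++k) m -= be[k] * xbar[k];
    return m;
  };

  for (int iter = 1; iter <= n_iter; ++iter) {
    bool adapting = iter <= n_burn;

    // --- intercept block ---
    {
      double d = R::rnorm(0.0, std::exp(ls_th[0]));
      double dll = 0.0;
      for (int i = 0; i < n; ++i) {
        llprop[i] = lik(i, eta[i] + d);
        dll += llprop[i] - ll[i];
      }
      double mu_old = mu_from_state(theta0, beta);
      double dpr = dnorm_log(mu_old + d, mu_mean, mu_var) -
                   dnorm_log(mu_old, mu_mean, mu_var);
      double lr = dll + dpr;
      double alpha = (lr >= 0) ? 1.0 : std::exp(lr);
      if (R::unif_rand() < alpha) {
        theta0 += d;
        for (int i = 0; i < n; ++i) { eta[i] += d; ll[i] = llprop[i]; }
        if (!adapting) acc_th[0] += 1.0;
      }
      adapt(ls_th[0], nprop_th[0], alpha, adapting);
    }

    // --- coefficient blocks ---
    for (int k = 0; k < p; ++k) {
      if (!update_beta[k]) continue;
      double d = R::rnorm(0.0, std::exp(ls_th[k + 1]));
      double dll = 0.0;
      const std::vector<int> &idx = colidx[k];
      for (size_t u = 0; u < idx.size(); ++u) {
        int i = idx[u];
        llprop[i] = lik(i, eta[i] + X(i, k) * d);
        dll += llprop[i] - ll[i];
      }
      double mu_old = mu_from_state(theta0, beta);
      double dpr = dnorm_log(beta[k] + d, beta_mean[k], beta_var) -
                   dnorm_log(beta[k], beta_mean[k], beta_var) +
                   dnorm_log(mu_old - xbar[k] * d, mu_mean, mu_var) -
                   dnorm_log(mu_old, mu_mean, mu_var);
      double lr = dll + dpr;
      double alpha = (lr >= 0) ? 1.0 : std::exp(lr);
      if (R::unif_rand() < alpha) {
        beta[k] += d;
        for (size_t u = 0; u < idx.size(); ++u) {
          int i = idx[u];
          eta[i] += X(i, k) * d;
          ll[i] = llprop[i];
        }
        if (!adapting) acc_th[k + 1] += 1.0;
      }
      adapt(ls_th[k + 1], nprop_th[k + 1], alpha, adapting);
    }

    // --- county random intercepts ---
    for (int j = 0; j < J; ++j) {
      double d = R::rnorm(0.0, std::exp(ls_b[j]));
      double dll = 0.0;
      const std::vector<int> &idx = cidx[j];
      for (size_t u = 0; u < idx.size(); ++u) {
        int i = idx[u];
        llprop[i] = lik(i, eta[i] + d);
        dll += llprop[i] - ll[i];
      }
      double bn = b[j] + d;
      double dpr = (b[j] * b[j] - bn * bn) / (2.0 * s2);
      double lr = dll + dpr;
      double alpha = (lr >= 0) ? 1.0 : std::exp(lr);
      if (R::unif_rand() < alpha) {
        b[j] = bn;
        for (size_t u = 0; u < idx.size(); ++u) {
          int i = idx[u];
          eta[i] += d;
          ll[i] = llprop[i];
        }
        if (!adapting) acc_b[j] += 1.0;
      }
      adapt(ls_b[j], nprop_b[j], alpha, adapting);
    }

    // --- likelihood-invariant translation moves ---
    // The intercept (and any county-constant covariate's coefficient) is
    // confounded with the county intercepts: shifting it while subtracting
    // the matching amount from every b_j leaves eta unchanged, so only the
    // priors enter the acceptance ratio. These moves decorrelate the slow
    // directions at negligible cost.
    if (swap_moves && J > 0) {
      {  // intercept vs. all county effects
        double d = R::rnorm(0.0, std::exp(ls_sw[0]));
        double mu_old = mu_from_state(theta0, beta);
        double dpr = dnorm_log(mu_old + d, mu_mean, mu_var) -
                     dnorm_log(mu_old, mu_mean, mu_var);
        for (int j = 0; j < J; ++j)
          dpr += (b[j] * b[j] - (b[j] - d) * (b[j] - d)) / (2.0 * s2);
        double alpha = (dpr >= 0) ? 1.0 : std::exp(dpr);
        if (R::unif_rand() < alpha) {
          theta0 += d;
          for (int j = 0; j < J; ++j) b[j] -= d;
        }
        adapt(ls_sw[0], nprop_sw[0], alpha, adapting);
      }
      if (update_beta[0] && county_x.size() == J) {
        // exposure coefficient vs. county effects (exposure county-constant)
        double d = R::rnorm(0.0, std::exp(ls_sw[1]));
        double mu_old = mu_from_state(theta0, beta);
        double dpr = dnorm_log(beta[0] + d, beta_mean[0], beta_var) -
                     dnorm_log(beta[0], beta_mean[0], beta_var) +
                     dnorm_log(mu_old - xbar[0] * d, mu_mean, mu_var) -
                     dnorm_log(mu_old, mu_mean, mu_var);
        for (int j = 0; j < J; ++j) {
          double bn = b[j] - d * county_x[j];
          dpr += (b[j] * b[j] - bn * bn) / (2.0 * s2);
        }
        double alpha = (dpr >= 0) ? 1.0 : std::exp(dpr);
        if (R::unif_rand() < alpha) {
          beta[0] += d;
          for (int j = 0; j < J; ++j) b[j] -= d * county_x[j];
        }
        adapt(ls_sw[1], nprop_sw[1], alpha, adapting);
      }
    }

    // --- random-effect variance (uniform prior; out-of-support rejected) ---
    if (update_s2) {
      double s2n = s2 + R::rnorm(0.0, std::exp(ls_s2));
      double alpha;
      if (s2n <= 0.0 || s2n >= s2_upper) {
        alpha = 0.0;
      } else {
        double sb2 = 0.0;
        for (int j = 0; j < J; ++j) sb2 += b[j] * b[j];
        double lr = -0.5 * J * (std::log(s2n) - std::log(s2)) -
                    0.5 * sb2 * (1.0 / s2n - 1.0 / s2);
        alpha = (lr >= 0) ? 1.0 : std::exp(lr);
      }
      if (R::unif_rand() < alpha) {
        s2 = s2n;
        if (!adapting) acc_s2 += 1.0;
      }
      adapt(ls_s2, nprop_s2, alpha, adapting);
    }

    if (!adapting) {
      ++n_post;
      if ((iter - n_burn) % thin == 0 && keep_row < n_keep) {
        draws(keep_row, 0) = mu_from_state(theta0, beta);
        for (int k = 0; k < p; ++k) draws(keep_row, k + 1) = beta[k];
        draws(keep_row, p + 1) = s2;
        for (int j = 0; j < J; ++j) draws(keep_row, p + 2 + j) = b[j];
        ++keep_row;
      }
    }
  }

  double denom = (n_post > 0) ? (double)n_post : 1.0;
  NumericVector acc_theta_out(p + 1);
  for (int k = 0; k <= p; ++k) acc_theta_out[k] = acc_th[k] / denom;
  NumericVector acc_b_out(J);
  for (int j = 0; j < J; ++j) acc_b_out[j] = acc_b[j] / denom;

  return List::create(_["draws"] = draws,
                      _["accept_fixed"] = acc_theta_out,
                      _["accept_county"] = acc_b_out,
                      _["accept_sigma0_sq"] = acc_s2 / denom);
}
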