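#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Spike-and-slab (SSVS) regression sampler.
//
// Model (on whatever scale the caller passes y and X):
//   y_i ~ Normal(alpha + sum_j beta_j X_ij + S * mu_t, sigma2 + S^2 * sigma2_t)
// with S = sum_j beta_j, beta_j = z_j * b_inc_j + (1 - z_j) * b_exc_j,
//   b_inc_j ~ Normal(0, g * tau^2), b_exc_j ~ Normal(0, tau^2),
//   z_j ~ Bernoulli(pi_incl), tau ~ HalfNormal(0, 1),
//   alpha ~ Normal(0, intercept_sd^2), sigma ~ HalfNormal(0, noise_scale).
// The S-dependent mean/variance terms are the closed-form marginalization of
// a latent per-sample log total abundance ~ Normal(mu_t, sigma2_t); passing
// mu_t = sigma2_t = 0 recovers a plain Gaussian regression (the clr-SS
// comparator path).
//
// Kernels, one full sweep per iteration:
//  * intercept: exact Gibbs (its conditional is Gaussian);
//  * log sigma2 and log tau: adaptive random-walk Metropolis (adaptation
//    frozen after burn-in so the retained chain has a fixed kernel);
//  * active coefficient copies: independence Metropolis-Hastings from the
//    conditional Gaussian obtained by treating the sample variance as fixed
//    at its current value (near-Gibbs; the S-dependence of the variance is
//    what the acceptance ratio corrects for);
//  * inactive copies: exact Gibbs from their prior;
//  * indicators: Metropolised Gibbs flips in random sweep order, jointly
//    proposing the newly active coefficient from the same conditional
//    Gaussian (an add/delete move with a matched reverse proposal).
// Uses R's RNG throughout so set.seed() gives bit-identical traces.

static const double LOG2PI = 1.837877066409345483560659472811;

struct Sampler {
  int n, p;
  const NumericVector y;
  const NumericMatrix X;
  double mu_t, sigma2_t, pi_incl, g, intercept_sd, noise_scale;
  double sqrtg;

  double alpha, ls2, lt; // log sigma2, log tau
  std::vector<double> bi, be;
  std::vector<int> z;
  std::vector<double> clin; // X %*% beta_eff
  double S;                 // sum(beta_eff)
  double cur_ll;

  Sampler(const NumericVector& y_, const NumericMatrix& X_)
    : y(y_), X(X_) {
    n = X_.nrow();
    p = X_.ncol();
  }

  double beta_eff(int j) const { return z[j] ? bi[j] : be[j]; }

  void refresh_linear() {
    S = 0.0;
    for (int j = 0; j < p; ++j) S += beta_eff(j);
    for (int i = 0; i < n; ++i) clin[i] = 0.0;
    for (int j = 0; j < p; ++j) {
      double b = beta_eff(j);
      if (b == 0.0) continue;
      for (int i = 0; i < n; ++i) clin[i] += b * X(i, j);
    }
  }

  double loglik(double a, double Ssum, double sigma2) const {
    double v = sigma2 + Ssum * Ssum * sigma2_t;
    double off = a + Ssum * mu_t;
    double ssr = 0.0;
    for (int i = 0; i < n; ++i) {
      double r = y[i] - off - clin[i];
      ssr += r * r;
    }
    return -0.5 * n * (LOG2PI + std::log(v)) - ssr / (2.0 * v);
  }

  // log likelihood when beta_eff[j] changes by delta
  double loglik_shift(int j, double delta, double sigma2) const {
    double Snew = S + delta;
    double v = sigma2 + Snew * Snew * sigma2_t;
    double off = alpha + Snew * mu_t;
    double ssr = 0.0;
    for (int i = 0; i < n; ++i) {
      double r = y[i] - off - clin[i] - delta * X(i, j);
      ssr += r * r;
    }
    return -0.5 * n * (LOG2PI + std::log(v)) - ssr / (2.0 * v);
  }

  void apply_shift(int j, double delta) {
    for (int i = 0; i < n; ++i) clin[i] += delta * X(i, j);
    S += delta;
  }

  // sufficient statistics of the conditional for coefficient j: regression
  // of the partial residual on w_i = X_ij + mu_t at current variance v.
  // b_cur is the value whose contribution is removed.
  void partial_stats(int j, double b_cur, double& ww, double& wpr) const {
    ww = 0.0; wpr = 0.0;
    double base = alpha + S * mu_t;
    for (int i = 0; i < n; ++i) {
      double w = X(i, j) + mu_t;
      double pr = y[i] - base - clin[i] + b_cur * w;
      ww += w * w;
      wpr += w * pr;
    }
  }

  static double log_halfnormal(double x, double scale) {
    return 0.5 * std::log(2.0 / M_PI) - std::log(scale)
      - x * x / (2.0 * scale * scale);
  }
  static double log_dnorm(double x, double mean, double sd) {
    double zd = (x - mean) / sd;
    return -0.5 * LOG2PI - std::log(sd) - 0.5 * zd * zd;
  }
};

// [[Rcpp::export(name = ".ssvs_chain_cpp")]]
List ssvs_chain_cpp(NumericVector y, NumericMatrix X,
                    double mu_t, double sigma2_t,
                    double pi_incl, double g,
                    double intercept_sd, double noise_scale,
                    int n_burn, int n_draws, int thin,
                    double init_alpha, double init_sigma2, double init_tau,
                    NumericVector init_bi, NumericVector init_be,
                    IntegerVector init_z) {
  Sampler s(y, X);
  s.mu_t = mu_t; s.sigma2_t = sigma2_t; s.pi_incl = pi_incl; s.g = g;
  s.intercept_sd = intercept_sd; s.noise_scale = noise_scale;
  s.sqrtg = std::sqrt(g);

  const int n = s.n, p = s.p;
  s.alpha = init_alpha;
  s.ls2 = std::log(init_sigma2);
  s.lt = std::log(init_tau);
  s.bi.assign(init_bi.begin(), init_bi.end());
  s.be.assign(init_be.begin(), init_be.end());
  s.z.assign(init_z.begin(), init_z.end());
  s.clin.assign(n, 0.0);
  s.refresh_linear();
  s.cur_ll = s.loglik(s.alpha, s.S, std::exp(s.ls2));
  if (!R_finite(s.cur_ll)) stop("non-finite log likelihood at initialization");

  double sc_ls2 = 0.5, sc_lt = 0.5; // adaptive RW scales

  const int n_keep = n_draws / thin;
  NumericVector out_alpha(n_keep), out_sigma2(n_keep), out_tau2(n_keep);
  NumericMatrix out_bi(n_keep, p), out_be(n_keep, p);
  IntegerMatrix out_z(n_keep, p);

  long acc_sigma = 0, acc_tau = 0, acc_beta = 0, try_beta = 0,
    acc_flip = 0, try_flip = 0;
  std::vector<int> order(p);

  RNGScope scope;
  const int total = n_burn + n_draws;
  int kept = 0;
  const double log_odds = std::log(pi_incl) - std::log(1.0 - pi_incl);

  for (int iter = 0; iter < total; ++iter) {
    const bool adapting = iter < n_burn;
    const double gamma = adapting ? 1.0 / std::sqrt(1.0 + iter) : 0.0;
    double sigma2 = std::exp(s.ls2);
    double tau = std::exp(s.lt);
    double tau2 = tau * tau;

    // --- intercept: exact Gibbs ---
    {
      double v = sigma2 + s.S * s.S * sigma2_t;
      double rs = 0.0;
      for (int i = 0; i < n; ++i) rs += y[i] - s.clin[i] - s.S * mu_t;
      double prec = n / v + 1.0 / (intercept_sd * intercept_sd);
      double mean = (rs / v) / prec;
      s.alpha = mean + norm_rand() / std::sqrt(prec);
      s.cur_ll = s.loglik(s.alpha, s.S, sigma2);
    }

    // --- residual variance (RW on log sigma2, HalfNormal prior on sigma) ---
    {
      double prop = s.ls2 + sc_ls2 * norm_rand();
      double sig_new = std::exp(prop / 2.0), sig_old = std::exp(s.ls2 / 2.0);
      double ll = s.loglik(s.alpha, s.S, std::exp(prop));
      double d = ll - s.cur_ll
        + Sampler::log_halfnormal(sig_new, noise_scale) + prop / 2.0
        - Sampler::log_halfnormal(sig_old, noise_scale) - s.ls2 / 2.0;
      bool acc = std::log(unif_rand()) < d;
      if (acc) { s.ls2 = prop; s.cur_ll = ll; sigma2 = std::exp(prop);
                 if (!adapting) ++acc_sigma; }
      if (adapting) sc_ls2 *= std::exp(gamma * ((acc ? 1.0 : 0.0) - 0.44));
    }

    // --- spike scale tau (RW on log tau; prior-only move over all betas) ---
    {
      double Sbi2 = 0.0, Sbe2 = 0.0;
      for (int j = 0; j < p; ++j) { Sbi2 += s.bi[j] * s.bi[j];
                                    Sbe2 += s.be[j] * s.be[j]; }
      double prop = s.lt + sc_lt * norm_rand();
      double tau_new = std::exp(prop);
      double lp_new = Sampler::log_halfnormal(tau_new, 1.0) + prop
        - p * std::log(s.sqrtg * tau_new) - Sbi2 / (2.0 * g * tau_new * tau_new)
        - p * std::log(tau_new) - Sbe2 / (2.0 * tau_new * tau_new);
      double lp_old = Sampler::log_halfnormal(tau, 1.0) + s.lt
        - p * std::log(s.sqrtg * tau) - Sbi2 / (2.0 * g * tau * tau)
        - p * std::log(tau) - Sbe2 / (2.0 * tau * tau);
      bool acc = std::log(unif_rand()) < lp_new - lp_old;
      if (acc) { s.lt = prop; tau = tau_new; tau2 = tau * tau;
                 if (!adapting) ++acc_tau; }
      if (adapting) sc_lt *= std::exp(gamma * ((acc ? 1.0 : 0.0) - 0.44));
    }

    // --- coefficients: independence MH from the conditional Gaussian on
    //     the active copy, prior Gibbs on the inactive copy ---
    for (int j = 0; j < p; ++j) {
      double slab_sd = s.sqrtg * tau;
      double prior_var = s.z[j] ? g * tau2 : tau2;
      double b_cur = s.beta_eff(j);
      double v = sigma2 + s.S * s.S * sigma2_t;
      double ww, wpr;
      s.partial_stats(j, b_cur, ww, wpr);
      double prec = ww / v + 1.0 / prior_var;
      double qm = (wpr / v) / prec, qs = 1.0 / std::sqrt(prec);
      double b_new = qm + qs * norm_rand();
      double ll = s.loglik_shift(j, b_new - b_cur, sigma2);
      // reverse proposal: same sufficient stats, variance at the new state
      double Snew = s.S + b_new - b_cur;
      double v_new = sigma2 + Snew * Snew * sigma2_t;
      double prec_r = ww / v_new + 1.0 / prior_var;
      double qm_r = (wpr / v_new) / prec_r, qs_r = 1.0 / std::sqrt(prec_r);
      double psd = std::sqrt(prior_var);
      double d = ll - s.cur_ll
        + Sampler::log_dnorm(b_new, 0.0, psd)
        - Sampler::log_dnorm(b_cur, 0.0, psd)
        + Sampler::log_dnorm(b_cur, qm_r, qs_r)
        - Sampler::log_dnorm(b_new, qm, qs);
      ++try_beta;
      if (std::log(unif_rand()) < d) {
        s.apply_shift(j, b_new - b_cur);
        if (s.z[j]) s.bi[j] = b_new; else s.be[j] = b_new;
        s.cur_ll = ll;
        ++acc_beta;
      }
      // inactive copy: conditional = prior
      if (s.z[j]) s.be[j] = tau * norm_rand();
      else s.bi[j] = slab_sd * norm_rand();
    }

    // --- indicator flips with jointly proposed coefficient (add/delete) ---
    for (int j = 0; j < p; ++j) order[j] = j;
    for (int k = p - 1; k > 0; --k) {
      int l = (int)std::floor(unif_rand() * (k + 1));
      if (l > k) l = k;
      std::swap(order[k], order[l]);
    }
    for (int k = 0; k < p; ++k) {
      int j = order[k];
      int z_cur = s.z[j];
      double var_cur = z_cur ? g * tau2 : tau2;   // prior var, current comp.
      double var_new = z_cur ? tau2 : g * tau2;   // prior var, target comp.
      double b_cur = s.beta_eff(j);
      double v = sigma2 + s.S * s.S * sigma2_t;
      double ww, wpr;
      s.partial_stats(j, b_cur, ww, wpr);
      // forward proposal for the newly active coefficient
      double prec_f = ww / v + 1.0 / var_new;
      double qm_f = (wpr / v) / prec_f, qs_f = 1.0 / std::sqrt(prec_f);
      double b_new = qm_f + qs_f * norm_rand();
      double ll = s.loglik_shift(j, b_new - b_cur, sigma2);
      // reverse proposal (from the flipped state back to z_cur)
      double Snew = s.S + b_new - b_cur;
      double v_new = sigma2 + Snew * Snew * sigma2_t;
      double prec_r = ww / v_new + 1.0 / var_cur;
      double qm_r = (wpr / v_new) / prec_r, qs_r = 1.0 / std::sqrt(prec_r);
      double d = ll - s.cur_ll
        + Sampler::log_dnorm(b_new, 0.0, std::sqrt(var_new))
        - Sampler::log_dnorm(b_cur, 0.0, std::sqrt(var_cur))
        + (z_cur ? -log_odds : log_odds)
        + Sampler::log_dnorm(b_cur, qm_r, qs_r)
        - Sampler::log_dnorm(b_new, qm_f, qs_f);
      ++try_flip;
      if (std::log(unif_rand()) < d) {
        s.apply_shift(j, b_new - b_cur);
        s.z[j] = 1 - z_cur;
        if (s.z[j]) { s.bi[j] = b_new; s.be[j] = tau * norm_rand(); }
        else { s.be[j] = b_new; s.bi[j] = s.sqrtg * tau * norm_rand(); }
        s.cur_ll = ll;
        ++acc_flip;
      }
    }

    // periodic exact recomputation to stop incremental drift
    if ((iter + 1) % 200 == 0) {
      s.refresh_linear();
      s.cur_ll = s.loglik(s.alpha, s.S, std::exp(s.ls2));
    }

    if (iter >= n_burn) {
      int d = iter - n_burn;
      if (d % thin == 0 && kept < n_keep) {
        out_alpha[kept] = s.alpha;
        out_sigma2[kept] = std::exp(s.ls2);
        out_tau2[kept] = std::exp(2.0 * s.lt);
        for (int j = 0; j < p; ++j) {
          out_bi(kept, j) = s.bi[j];
          out_be(kept, j) = s.be[j];
          out_z(kept, j) = s.z[j];
        }
        ++kept;
      }
    }
  }

  double denom = std::max(1L, (long)(total - n_burn));
  return List::create(
    _["alpha"] = out_alpha, _["sigma2"] = out_sigma2, _["tau2"] = out_tau2,
    _["beta_included"] = out_bi, _["beta_excluded"] = out_be,
    _["indicators"] = out_z,
    _["diagnostics"] = List::create(
      _["accept_sigma"] = acc_sigma / denom,
      _["accept_tau"] = acc_tau / denom,
      _["accept_beta"] = try_beta ? (double)acc_beta / try_beta : NA_REAL,
      _["accept_flip"] = try_flip ? (double)acc_flip / try_flip : NA_REAL));
}
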