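// Metropolis-within-Gibbs sampler for the multi-season occupancy model
// with imperfect detection: exact Bernoulli full conditionals for the
// latent states z[i,t], adaptive random-walk Metropolis for the logit-scale
// occupancy (beta) and detection (alpha) coefficients, and conjugate Beta
// draws for the colonization (gamma) and extinction (epsilon) constants
// under their Uniform(0,1) priors. All randomness comes from R's RNG so
// runs are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static inline double log_plogis(double x) { return -R::log1pexp(-x); }

static inline double bern_ll(int y, double eta) {
  // log Bernoulli(y | plogis(eta)), stable for large |eta|
  return y == 1 ? log_plogis(eta) : log_plogis(-eta);
}

static inline double lse2(double a, double b) {
  double m = a > b ? a : b;
  if (!R_finite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Marginal log-likelihood of one cell: forward recursion over latent
// states, closed within seasons, open between seasons.
static double cell_marginal(int T, const double* lldet1, const int* anydet,
                            double psi, double gam, double eps) {
  const double NEG_INF = R_NegInf;
  double f1 = std::log(psi) + lldet1[0];
  double f0 = std::log1p(-psi) + (anydet[0] ? NEG_INF : 0.0);
  for (int t = 1; t < T; ++t) {
    double g1 = lse2(f1 + std::log1p(-eps), f0 + std::log(gam)) + lldet1[t];
    double g0 = lse2(f1 + std::log(eps), f0 + std::log1p(-gam)) +
      (anydet[t] ? NEG_INF : 0.0);
    f1 = g1; f0 = g0;
  }
  return lse2(f1, f0);
}

// Recompute per cell-year: sum of detection log-likelihood given presence.
static void compute_lldet1(const IntegerVector& y, const IntegerVector& cell,
                           const IntegerVector& year, const NumericVector& eta,
                           int T, std::vector<double>& lldet1) {
  std::fill(lldet1.begin(), lldet1.end(), 0.0);
  int nobs = y.size();
  for (int r = 0; r < nobs; ++r) {
    lldet1[cell[r] * T + year[r]] += bern_ll(y[r], eta[r]);
  }
}

// [[Rcpp::export]]
List occu_chain_cpp(IntegerVector y, IntegerVector cell, IntegerVector year,
                    NumericMatrix W, NumericMatrix X, int n, int T,
                    int n_iter, int n_burn, int thin, double prior_sd,
                    NumericVector beta_init, NumericVector alpha_init,
                    double gamma_init, double epsilon_init,
                    double init_scale = 0.5) {
  const int P = X.ncol(), Q = W.ncol(), nobs = y.size();
  const double NEG_INF = R_NegInf;
  if (X.nrow() != n) stop("X must have one row per cell");
  if (W.nrow() != nobs) stop("W must have one row per detection record");

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> alpha(alpha_init.begin(), alpha_init.end());
  double gam = gamma_init, eps = epsilon_init;
  if (gam <= 0 || gam >= 1 || eps <= 0 || eps >= 1)
    stop("gamma/epsilon inits must be in (0,1)");

  // caches
  NumericVector eta_det(nobs), eta_occ(n);
  for (int r = 0; r < nobs; ++r) {
    double s = 0; for (int k = 0; k < Q; ++k) s += W(r, k) * alpha[k];
    eta_det[r] = s;
  }
  for (int i = 0; i < n; ++i) {
    double s = 0; for (int k = 0; k < P; ++k) s += X(i, k) * beta[k];
    eta_occ[i] = s;
  }
  std::vector<double> lldet1((size_t)n * T);
  std::vector<int> anydet((size_t)n * T, 0), nocc((size_t)n * T, 0);
  for (int r = 0; r < nobs; ++r) {
    int k = cell[r] * T + year[r];
    nocc[k]++; if (y[r] == 1) anydet[k] = 1;
  }
  compute_lldet1(y, cell, year, eta_det, T, lldet1);

  // latent states: start at 1 (consistent with the detection constraint)
  std::vector<int> z((size_t)n * T, 1);

  // adaptive proposal scales
  std::vector<double> scale_b(P, init_scale), scale_a(Q, init_scale);
  std::vector<int> acc_b(P, 0), acc_a(Q, 0);
  const int batch = 50;
  int batch_no = 0;

  const int S = n_iter / thin;
  NumericMatrix out_beta(S, P), out_alpha(S, Q), out_ll(S, n);
  NumericVector out_gamma(S), out_eps(S);
  IntegerMatrix out_z(S, n * T);
  std::vector<double> acc_tot_b(P, 0), acc_tot_a(Q, 0);
  int s_out = 0;

  const int total = n_burn + n_iter;  // RNG scope handled by the wrapper
  for (int it = 0; it < total; ++it) {
    // --- z updates: exact Bernoulli full conditionals ------------------
    for (int i = 0; i < n; ++i) {
      double psi = 1.0 / (1.0 + std::exp(-eta_occ[i]));
      for (int t = 0; t < T; ++t) {
        int k = i * T + t;
        if (anydet[k]) { z[k] = 1; continue; }
        double l1 = lldet1[k], l0 = 0.0;
        if (t == 0) {
          l1 += std::log(psi); l0 += std::log1p(-psi);
        } else {
          double prev1 = z[i * T + t - 1];
          l1 += prev1 ? std::log1p(-eps) : std::log(gam);
          l0 += prev1 ? std::log(eps) : std::log1p(-gam);
        }
        if (t < T - 1) {
          int nxt = z[i * T + t + 1];
          l1 += nxt ? std::log1p(-eps) : std::log(eps);
          l0 += nxt ? std::log(gam) : std::log1p(-gam);
        }
        double p1;
        if (l1 == NEG_INF) p1 = 0.0;
        else if (l0 == NEG_INF) p1 = 1.0;
        else p1 = 1.0 / (1.0 + std::exp(l0 - l1));
        z[k] = (unif_rand() < p1) ? 1 : 0;
      }
    }

    // --- gamma, epsilon: conjugate Beta full conditionals --------------
    if (T > 1) {
      int n01 = 0, n00 = 0, n10 = 0, n11 = 0;
      for (int i = 0; i < n; ++i) {
        for (int t = 1; t < T; ++t) {
          int prev = z[i * T + t - 1], cur = z[i * T + t];
          if (prev == 0) { if (cur) n01++; else n00++; }
          else           { if (cur) n11++; else n10++; }
        }
      }
      gam = R::rbeta(1.0 + n01, 1.0 + n00);
      eps = R::rbeta(1.0 + n10, 1.0 + n11);
    } else {
      gam = R::rbeta(1.0, 1.0);
      eps = R::rbeta(1.0, 1.0);
    }

    // --- beta: per-coordinate random-walk Metropolis -------------------
    for (int k = 0; k < P; ++k) {
      double d = scale_b[k] * norm_rand();
      double cur = 0, prop = 0;
      for (int i = 0; i < n; ++i) {
        double e0 = eta_occ[i], e1 = e0 + X(i, k) * d;
        int z1 = z[i * T];  // first-season state
        cur += z1 ? log_plogis(e0) : log_plogis(-e0);
        prop += z1 ? log_plogis(e1) : log_plogis(-e1);
      }
      double bk = beta[k], bp = bk + d;
      double logr = prop - cur +
        R::dnorm(bp, 0.0, prior_sd, 1) - R::dnorm(bk, 0.0, prior_sd, 1);
      if (std::log(unif_rand()) < logr) {
        beta[k] = bp;
        for (int i = 0; i < n; ++i) eta_occ[i] += X(i, k) * d;
        acc_b[k]++; if (it >= n_burn) acc_tot_b[k]++;
      }
    }

    // --- alpha: per-coordinate random-walk Metropolis ------------------
    for (int k = 0; k < Q; ++k) {
      double d = scale_a[k] * norm_rand();
      double cur = 0, prop = 0;
      for (int r = 0; r < nobs; ++r) {
        if (!z[cell[r] * T + year[r]]) continue;  // only occupied cell-years
        double e0 = eta_det[r], e1 = e0 + W(r, k) * d;
        cur += bern_ll(y[r], e0);
        prop += bern_ll(y[r], e1);
      }
      double ak = alpha[k], ap = ak + d;
      double logr = prop - cur +
        R::dnorm(ap, 0.0, prior_sd, 1) - R::dnorm(ak, 0.0, prior_sd, 1);
      if (std::log(unif_rand()) < logr) {
        alpha[k] = ap;
        for (int r = 0; r < nobs; ++r) eta_det[r] += W(r, k) * d;
        compute_lldet1(y, cell, year, eta_det, T, lldet1);
        acc_a[k]++; if (it >= n_burn) acc_tot_a[k]++;
      }
    }

    // --- proposal adaptation during burn-in ----------------------------
    if (it < n_burn && (it + 1) % batch == 0) {
      batch_no++;
      double step = std::min(0.1, 1.0 / std::sqrt((double)batch_no));
      for (int k = 0; k < P; ++k) {
        scale_b[k] *= std::exp(((double)acc_b[k] / batch > 0.44) ? step : -step);
        acc_b[k] = 0;
      }
      for (int k = 0; k < Q; ++k) {
        scale_a[k] *= std::exp(((double)acc_a[k] / batch > 0.44) ? step : -step);
        acc_a[k] = 0;
      }
    }

    // --- retain ---------------------------------------------------------
    if (it >= n_burn && (it - n_burn + 1) % thin == 0) {
      for (int k = 0; k < P; ++k) out_beta(s_out, k) = beta[k];
      for (int k = 0; k < Q; ++k) out_alpha(s_out, k) = alpha[k];
      out_gamma[s_out] = gam; out_eps[s_out] = eps;
      for (int k = 0; k < n * T; ++k) out_z(s_out, k) = z[k];
      for (int i = 0; i < n; ++i) {
        double psi = 1.0 / (1.0 + std::exp(-eta_occ[i]));
        out_ll(s_out, i) = cell_marginal(T, &lldet1[(size_t)i * T],
                                         &anydet[(size_t)i * T], psi, gam, eps);
      }
      s_out++;
    }
  }

  double n_post = (double)n_iter;
  NumericVector acc_rate_b(P), acc_rate_a(Q);
  for (int k = 0; k < P; ++k) acc_rate_b[k] = acc_tot_b[k] / n_post;
  for (int k = 0; k < Q; ++k) acc_rate_a[k] = acc_tot_a[k] / n_post;
  return List::create(
    _["beta"] = out_beta, _["alpha"] = out_alpha,
    _["gamma"] = out_gamma, _["epsilon"] = out_eps,
    _["z"] = out_z, _["loglik"] = out_ll,
    _["accept_beta"] = acc_rate_b, _["accept_alpha"] = acc_rate_a,
    _["scale_beta"] = NumericVector(scale_b.begin(), scale_b.end()),
    _["scale_alpha"] = NumericVector(scale_a.begin(), scale_a.end()));
}

// Pointwise marginal log-likelihood matrix: one row per posterior draw,
// one column per cell, latent states marginalized analytically.
// [[Rcpp::export]]
NumericMatrix pointwise_loglik_cpp(NumericMatrix beta, NumericMatrix alpha,
                                   NumericVector gamma, NumericVector epsilon,
                                   NumericMatrix X, NumericMatrix W,
                                   IntegerVector y, IntegerVector cell,
                                   IntegerVector year, int n, int T) {
  const int S = beta.nrow(), P = X.ncol(), Q = W.ncol(), nobs = y.size();
  if (alpha.nrow() != S || gamma.size() != S || epsilon.size() != S)
    stop("draw blocks have inconsistent numbers of draws");
  std::vector<int> anydet((size_t)n * T, 0);
  for (int r = 0; r < nobs; ++r) {
    if (y[r] == 1) anydet[cell[r] * T + year[r]] = 1;
  }
  NumericMatrix out(S, n);
  std::vector<double> lldet1((size_t)n * T);
  NumericVector eta(nobs);
  for (int s = 0; s < S; ++s) {
    for (int r = 0; r < nobs; ++r) {
      double e = 0; for (int k = 0; k < Q; ++k) e += W(r, k) * alpha(s, k);
      eta[r] = e;
    }
    compute_lldet1(y, cell, year, eta, T, lldet1);
    for (int i = 0; i < n; ++i) {
      double xb = 0; for (int k = 0; k < P; ++k) xb += X(i, k) * beta(s, k);
      double psi = 1.0 / (1.0 + std::exp(-xb));
      out(s, i) = cell_marginal(T, &lldet1[(size_t)i * T],
                                &anydet[(size_t)i * T], psi,
                                gamma[s], epsilon[s]);
    }
  }
  return out;
}
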