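#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the mixture model y = Xb + Zu + e.
//
// Marker j carries effect u_j which is exactly zero with prior probability
// pi and, with probability 1 - pi, is drawn N(0, sigma2_uj).  BayesC uses a
// single slab variance common to all markers, updated from its scaled
// inverse chi-square full conditional; BayesB keeps a locus-specific
// variance for every marker, refreshed from its full conditional when the
// marker is in the model and from the prior when it is not (exact Gibbs via
// data augmentation, so the chain targets the usual BayesB posterior).
//
// The inclusion indicator is sampled from the marginal full conditional
// based on r_j = z_j' y_corr, the marker's score on the data with its own
// contribution added back; u_j is then drawn from its conditional normal.
// Fixed effects have flat priors.  Residual variance has a scaled inverse
// chi-square prior.  All randomness comes from R's RNG, so set.seed() on
// the R side makes a run fully reproducible.  Marker update order is the
// column order of Z (fixed, no permutation).
//
// Per stored sample we also record sigma2_g, the variance across animals of
// the genomic values g = Zu (n-1 denominator), which is the genetic
// variance definition used downstream for windows and heritability.

static inline double dot_cols(const double* a, const double* b, const int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += a[i] * b[i];
  return s;
}

// [[Rcpp::export]]
List wgr_mcmc_cpp(const NumericVector y,
                  const NumericMatrix X,
                  const NumericMatrix Z,
                  const double pi,
                  const double nu_u, const double s2_u,
                  const double nu_e, const double s2_e,
                  const int variant,          // 0 = BayesC, 1 = BayesB
                  const int n_iter, const int n_burn, const int thin,
                  const bool update_var_u, const bool update_var_e,
                  const double sigma2_u_init, const double sigma2_e_init) {
  const int n = y.size();
  const int m = Z.ncol();
  const int p = X.ncol();
  if (X.nrow() != n || Z.nrow() != n)
    stop("design matrices not conformable with y");
  if (n_burn >= n_iter) stop("n_burn must be smaller than n_iter");
  if ((n_iter - n_burn) % thin != 0)
    stop("(n_iter - n_burn) must be divisible by thin");
  const int n_stored = (n_iter - n_burn) / thin;

  std::vector<double> b(p, 0.0), u(m, 0.0), e(n), g(n, 0.0);
  std::vector<int> delta(m, 0);
  std::vector<double> sigma2_uj;                  // BayesB locus variances
  double sigma2_u = sigma2_u_init;                // BayesC common variance
  double sigma2_e = sigma2_e_init;
  if (variant == 1) sigma2_uj.assign(m, sigma2_u_init);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  std::vector<double> xtx(p), ztz(m);
  for (int k = 0; k < p; ++k) xtx[k] = dot_cols(&X(0, k), &X(0, k), n);
  for (int j = 0; j < m; ++j) ztz[j] = dot_cols(&Z(0, j), &Z(0, j), n);

  NumericMatrix U(n_stored, m), B(n_stored, p);
  NumericVector S2E(n_stored), S2U(n_stored), S2G(n_stored);
  IntegerVector NINC(n_stored);

  const double log_prior_odds =
      (pi <= 0.0) ? R_PosInf : (pi >= 1.0 ? R_NegInf : std::log1p(-pi) - std::log(pi));

  for (int iter = 1; iter <= n_iter; ++iter) {
    // -- fixed effects, flat prior ------------------------------------
    for (int k = 0; k < p; ++k) {
      if (xtx[k] <= 0.0) continue;             // all-zero column (e.g. CG
      const double* xk = &X(0, k);             // level absent in subset)
      double rhs = dot_cols(xk, e.data(), n) + xtx[k] * b[k];
      double mean = rhs / xtx[k];
      double bnew = mean + norm_rand() * std::sqrt(sigma2_e / xtx[k]);
      double d = bnew - b[k];
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] -= xk[i] * d;
      b[k] = bnew;
    }

    // -- markers ------------------------------------------------------
    int n_inc = 0;
    double ss_u = 0.0;                          // sum u^2 over included
    for (int j = 0; j < m; ++j) {
      const double zz = ztz[j];
      const double* zj = &Z(0, j);
      double s2j = (variant == 1) ? sigma2_uj[j] : sigma2_u;
      double unew = 0.0;
      int dnew = 0;
      if (zz > 0.0 && pi < 1.0 && s2j > 0.0) {
        double rhs = dot_cols(zj, e.data(), n) + zz * u[j];
        double v0 = zz * sigma2_e;
        double v1 = v0 + zz * zz * s2j;
        double logodds = log_prior_odds + 0.5 * (std::log(v0) - std::log(v1)) +
                         0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
        double p_inc = (logodds == R_PosInf)
                           ? 1.0
                           : (logodds == R_NegInf ? 0.0 : 1.0 / (1.0 + std::exp(-logodds)));
        if (unif_rand() < p_inc) {
          double C = zz + sigma2_e / s2j;
          unew = rhs / C + norm_rand() * std::sqrt(sigma2_e / C);
          dnew = 1;
        }
      }
      double d = unew - u[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) { e[i] -= zj[i] * d; g[i] += zj[i] * d; }
      }
      u[j] = unew;
      delta[j] = dnew;
      if (dnew) { ++n_inc; ss_u += unew * unew; }
      if (variant == 1 && update_var_u) {
        // refresh the locus variance: full conditional when in the model,
        // prior draw when out (keeps the augmented chain irreducible)
        if (dnew)
          sigma2_uj[j] = (nu_u * s2_u + unew * unew) / Rf_rchisq(nu_u + 1.0);
        else
          sigma2_uj[j] = (nu_u * s2_u) / Rf_rchisq(nu_u);
      }
    }

    // -- variance components ------------------------------------------
    if (variant == 0 && update_var_u)
      sigma2_u = (nu_u * s2_u + ss_u) / Rf_rchisq(nu_u + (double)n_inc);
    if (update_var_e) {
      double sse = dot_cols(e.data(), e.data(), n);
      sigma2_e = (nu_e * s2_e + sse) / Rf_rchisq(nu_e + (double)n);
    }

    // -- storage -------------------------------------------------------
    if (iter > n_burn && (iter - n_burn) % thin == 0) {
      int s = (iter - n_burn) / thin - 1;
      for (int j = 0; j < m; ++j) U(s, j) = u[j];
      for (int k = 0; k < p; ++k) B(s, k) = b[k];
      S2E[s] = sigma2_e;
      S2U[s] = (variant == 0) ? sigma2_u : NA_REAL;
      double gm = 0.0;
      for (int i = 0; i < n; ++i) gm += g[i];
      gm /= n;
      double gv = 0.0;
      for (int i = 0; i < n; ++i) gv += (g[i] - gm) * (g[i] - gm);
      S2G[s] = (n > 1) ? gv / (n - 1) : 0.0;
      NINC[s] = n_inc;
    }
    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["u"] = U, _["b"] = B, _["sigma2_e"] = S2E,
                      _["sigma2_u"] = S2U, _["sigma2_g"] = S2G,
                      _["n_included"] = NINC);
}
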