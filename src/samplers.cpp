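// Gibbs samplers for whole-genome regression (Bayesian ridge, Bayes A,
// Bayes B, Bayes C-pi, Bayesian LASSO) and the pedigree animal model.
// All randomness goes through R's RNG so that set.seed() in R makes
// chains bit-reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// scaled-inverse-chi-squared draw: nu * S / chisq_nu
static inline double rscinvchisq(double nu, double S) {
  return nu * S / R::rchisq(nu);
}

// inverse-Gaussian draw (Michael-Schucany-Haas)
static inline double rinvgauss(double mu, double lambda) {
  double v = R::norm_rand();
  double y = v * v;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
    (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  double u = R::unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// residual-updating draw for one regression coefficient with normal prior
// variance `pv` (pv = R_PosInf -> flat prior). e is the current residual
// (y - fitted). Returns the new coefficient and updates e in place.
static inline double update_coef(const double* z, int n, double zsq,
                                 std::vector<double>& e, double old,
                                 double pv, double sigma_e2) {
  double rhs = 0.0;
  for (int i = 0; i < n; ++i) rhs += z[i] * e[i];
  rhs += zsq * old;
  double C = zsq + ((pv == R_PosInf) ? 0.0 : sigma_e2 / pv);
  double mean = rhs / C;
  double newb = mean + std::sqrt(sigma_e2 / C) * R::norm_rand();
  double diff = old - newb;
  for (int i = 0; i < n; ++i) e[i] += z[i] * diff;
  return newb;
}

// model codes
enum { BRR = 0, BA = 1, BB = 2, BC = 3, BL = 4 };

// [[Rcpp::export]]
List gibbs_wgr_cpp(NumericVector y, NumericMatrix X, NumericMatrix Z,
                   int model, double nu_m, double S_m,
                   double nu_e, double S_e,
                   double pi0, bool pi_fixed,
                   double phi1, double phi2, double lambda2_init,
                   bool bl_printed_rate,
                   int niter, int burnin, int thin) {
  const int n = y.size();
  const int px = X.ncol();
  const int p = Z.ncol();
  if (X.nrow() != n || Z.nrow() != n) stop("design rows must match y");
  const int nret = (niter - burnin) / thin;
  if (nret < 1) stop("no retained samples; check iterations/burn_in/thin");

  // fixed-effect columns with zero sum of squares (e.g. a design block
  // absent from a training fold) are skipped: all-zero regressors
  std::vector<double> xsq(px), zsq(p);
  for (int k = 0; k < px; ++k) {
    double s = 0.0; for (int i = 0; i < n; ++i) s += X(i, k) * X(i, k);
    xsq[k] = s;
  }
  for (int j = 0; j < p; ++j) {
    double s = 0.0; for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zsq[j] = s;
  }

  // state
  std::vector<double> beta(px, 0.0), m(p, 0.0);
  std::vector<double> sig_mi(p, S_m);      // per-marker variances (BA/BB)
  std::vector<double> tau2(p, 1.0);        // BL latent scales
  std::vector<int> delta(p, 1);            // inclusion indicators (BB/BC)
  double sigma_m2 = S_m;                   // common slab variance (BRR/BC)
  double sigma_e2 = S_e;
  double pi_zero = pi0;
  double lambda2 = lambda2_init;

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  // storage
  NumericMatrix beta_s(nret, px), m_s(nret, p);
  NumericVector sigma_e2_s(nret), sigma_m2_s(nret), pi_s(nret), lambda2_s(nret);
  NumericMatrix var_s((model == BA || model == BB) ? nret : 0,
                      (model == BA || model == BB) ? p : 0);
  NumericMatrix tau2_s(model == BL ? nret : 0, model == BL ? p : 0);
  IntegerMatrix delta_s((model == BB || model == BC) ? nret : 0,
                        (model == BB || model == BC) ? p : 0);

  int kept = 0;
  for (int it = 0; it < niter; ++it) {
    // fixed effects, flat prior
    for (int k = 0; k < px; ++k)
      if (xsq[k] > 0.0)
        beta[k] = update_coef(&X(0, k), n, xsq[k], e, beta[k],
                              R_PosInf, sigma_e2);

    if (model == BRR || model == BA) {
      for (int j = 0; j < p; ++j) {
        if (zsq[j] <= 0.0) { m[j] = 0.0; continue; }
        double pv = (model == BRR) ? sigma_m2 : sig_mi[j];
        m[j] = update_coef(&Z(0, j), n, zsq[j], e, m[j], pv, sigma_e2);
      }
      if (model == BRR) {
        double ssm = 0.0; for (int j = 0; j < p; ++j) ssm += m[j] * m[j];
        sigma_m2 = (ssm + nu_m * S_m) / R::rchisq(nu_m + p);
      } else {
        for (int j = 0; j < p; ++j)
          sig_mi[j] = (m[j] * m[j] + nu_m * S_m) / R::rchisq(nu_m + 1.0);
      }
    } else if (model == BB || model == BC) {
      int n_in = 0;
      for (int j = 0; j < p; ++j) {
        if (zsq[j] <= 0.0) { m[j] = 0.0; delta[j] = 0; continue; }
        double sj = (model == BC) ? sigma_m2 : sig_mi[j];
        // r = z_j' e with marker j removed from the fit
        double r = 0.0;
        const double* z = &Z(0, j);
        for (int i = 0; i < n; ++i) r += z[i] * e[i];
        r += zsq[j] * m[j];
        double v = zsq[j];
        // marginal likelihood ratio include : exclude
        double log_ratio = 0.5 * std::log(sigma_e2 / (sigma_e2 + v * sj)) +
          0.5 * r * r * sj / (sigma_e2 * (sigma_e2 + v * sj));
        double odds = (1.0 - pi_zero) / pi_zero * std::exp(log_ratio);
        double p_in = odds / (1.0 + odds);
        double old = m[j];
        if (R::unif_rand() < p_in) {
          double C = v + sigma_e2 / sj;
          m[j] = r / C + std::sqrt(sigma_e2 / C) * R::norm_rand();
          delta[j] = 1; ++n_in;
        } else {
          m[j] = 0.0; delta[j] = 0;
        }
        if (m[j] != old) {
          double diff = old - m[j];
          for (int i = 0; i < n; ++i) e[i] += z[i] * diff;
        }
      }
      if (model == BC) {
        double ssm = 0.0; for (int j = 0; j < p; ++j) ssm += m[j] * m[j];
        sigma_m2 = (ssm + nu_m * S_m) / R::rchisq(nu_m + n_in);
      } else {
        for (int j = 0; j < p; ++j) {
          if (delta[j])
            sig_mi[j] = (m[j] * m[j] + nu_m * S_m) / R::rchisq(nu_m + 1.0);
          else
            sig_mi[j] = rscinvchisq(nu_m, S_m);  // refresh from the prior
        }
      }
      if (!pi_fixed) {
        int n_zero = p - n_in;
        pi_zero = R::rbeta(1.0 + n_zero, 1.0 + n_in);
        if (pi_zero < 1e-6) pi_zero = 1e-6;
        if (pi_zero > 1.0 - 1e-6) pi_zero = 1.0 - 1e-6;
      }
    } else if (model == BL) {
      for (int j = 0; j < p; ++j) {
        if (zsq[j] <= 0.0) { m[j] = 0.0; continue; }
        // prior var of m_j is tau2_j * sigma_e2
        double C = zsq[j] + 1.0 / tau2[j];
        double r = 0.0;
        const double* z = &Z(0, j);
        for (int i = 0; i < n; ++i) r += z[i] * e[i];
        r += zsq[j] * m[j];
        double old = m[j];
        m[j] = r / C + std::sqrt(sigma_e2 / C) * R::norm_rand();
        double diff = old - m[j];
        for (int i = 0; i < n; ++i) e[i] += z[i] * diff;
        double m2 = m[j] * m[j];
        if (m2 < 1e-12) m2 = 1e-12;
        double mu = std::sqrt(lambda2 * sigma_e2 / m2);
        double invtau2 = rinvgauss(mu, lambda2);
        tau2[j] = 1.0 / invtau2;
      }
      double sumtau = 0.0;
      for (int j = 0; j < p; ++j) sumtau += tau2[j];
      // tau2_j ~ Exp(rate lambda2/2) (Park-Casella) or Exp(rate lambda2)
      double rate = phi2 + (bl_printed_rate ? sumtau : 0.5 * sumtau);
      lambda2 = R::rgamma(phi1 + p, 1.0 / rate);
    }

    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma_e2 = (sse + nu_e * S_e) / R::rchisq(nu_e + n);
    if (!R_finite(sigma_e2) || sigma_e2 > 1e12)
      stop("residual variance diverged at iteration %d", it + 1);

    if (it >= burnin && (it - burnin) % thin == 0 && kept < nret) {
      for (int k = 0; k < px; ++k) beta_s(kept, k) = beta[k];
      for (int j = 0; j < p; ++j) m_s(kept, j) = m[j];
      sigma_e2_s[kept] = sigma_e2;
      sigma_m2_s[kept] = sigma_m2;
      pi_s[kept] = pi_zero;
      lambda2_s[kept] = lambda2;
      if (model == BA || model == BB)
        for (int j = 0; j < p; ++j) var_s(kept, j) = sig_mi[j];
      if (model == BL)
        for (int j = 0; j < p; ++j) tau2_s(kept, j) = tau2[j];
      if (model == BB || model == BC)
        for (int j = 0; j < p; ++j) delta_s(kept, j) = delta[j];
      ++kept;
    }
  }

  return List::create(
    _["beta"] = beta_s, _["m"] = m_s,
    _["sigma_e2"] = sigma_e2_s, _["sigma_m2"] = sigma_m2_s,
    _["pi"] = pi_s, _["lambda2"] = lambda2_s,
    _["sigma_mi2"] = var_s, _["tau2"] = tau2_s, _["delta"] = delta_s);
}

// Animal model: y = X beta + a[zind] + e, a ~ N(0, A sigma_a2).
// Ainv passed in compressed sparse column form (0-based p/i/x).
// [[Rcpp::export]]
List gibbs_animal_cpp(NumericVector y, NumericMatrix X, IntegerVector zind,
                      IntegerVector Ap, IntegerVector Aji, NumericVector Ax,
                      int q, double nu_a, double S_a, double nu_e, double S_e,
                      int niter, int burnin, int thin) {
  const int n = y.size();
  const int px = X.ncol();
  if (X.nrow() != n || zind.size() != n) stop("design rows must match y");
  const int nret = (niter - burnin) / thin;
  if (nret < 1) stop("no retained samples; check iterations/burn_in/thin");

  // records per individual
  std::vector<std::vector<int>> recs(q);
  for (int i = 0; i < n; ++i) {
    int u = zind[i];
    if (u < 0 || u >= q) stop("individual index out of range");
    recs[u].push_back(i);
  }
  std::vector<double> xsq(px);
  for (int k = 0; k < px; ++k) {
    double s = 0.0; for (int i = 0; i < n; ++i) s += X(i, k) * X(i, k);
    xsq[k] = s;  // zero-ssq columns are skipped below
  }

  std::vector<double> beta(px, 0.0), a(q, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];
  double sigma_a2 = S_a, sigma_e2 = S_e;

  NumericMatrix beta_s(nret, px), a_s(nret, q);
  NumericVector sa_s(nret), se_s(nret);

  int kept = 0;
  for (int it = 0; it < niter; ++it) {
    for (int k = 0; k < px; ++k)
      if (xsq[k] > 0.0)
        beta[k] = update_coef(&X(0, k), n, xsq[k], e, beta[k],
                              R_PosInf, sigma_e2);

    // single-site updates of additive effects
    for (int u = 0; u < q; ++u) {
      double aii = 0.0, cross = 0.0;
      for (int idx = Ap[u]; idx < Ap[u + 1]; ++idx) {
        int v = Aji[idx];
        if (v == u) aii += Ax[idx];
        else cross += Ax[idx] * a[v];
      }
      double nrec = (double)recs[u].size();
      double C = nrec / sigma_e2 + aii / sigma_a2;
      double rhs = -cross / sigma_a2;
      for (int r : recs[u]) rhs += (e[r] + a[u]) / sigma_e2;
      double old = a[u];
      a[u] = rhs / C + std::sqrt(1.0 / C) * R::norm_rand();
      double diff = old - a[u];
      for (int r : recs[u]) e[r] += diff;
    }

    // a' Ainv a
    double quad = 0.0;
    for (int u = 0; u < q; ++u)
      for (int idx = Ap[u]; idx < Ap[u + 1]; ++idx)
        quad += a[Aji[idx]] * Ax[idx] * a[u];
    sigma_a2 = (quad + nu_a * S_a) / R::rchisq(nu_a + q);

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma_e2 = (sse + nu_e * S_e) / R::rchisq(nu_e + n);
    if (!R_finite(sigma_e2) || sigma_e2 > 1e12)
      stop("residual variance diverged at iteration %d", it + 1);

    if (it >= burnin && (it - burnin) % thin == 0 && kept < nret) {
      for (int k = 0; k < px; ++k) beta_s(kept, k) = beta[k];
      for (int u = 0; u < q; ++u) a_s(kept, u) = a[u];
      sa_s[kept] = sigma_a2;
      se_s[kept] = sigma_e2;
      ++kept;
    }
  }

  return List::create(_["beta"] = beta_s, _["a"] = a_s,
                      _["sigma_a2"] = sa_s, _["sigma_e2"] = se_s);
}
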