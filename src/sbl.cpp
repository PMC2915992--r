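#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Sparse Bayesian learning fit of a piecewise-constant model
//
//   y = F w + e,   e ~ N(0, sigma2 I)
//
// where F is the normalized step basis: column m (m = 1..M-1) is the
// zero-mean, unit-norm vector that is constant up to probe m and jumps
// after it.  Its Gram matrix is G[m,n] = u(m)/u(n) for m <= n with
// u(m) = sqrt(m/(M-m)), i.e. a Markov-type kernel whose inverse is
// tridiagonal for ANY subset of active columns.  Every quantity below is
// therefore computed with O(k) tridiagonal recursions plus one O(M)
// residual pass per sweep; no M x M object is ever formed.
//
// Hierarchical prior: w_m ~ N(0, 1/alpha_m), alpha_m ~ Gamma(a, b).
// EM-style sweep:
//   posterior: Sigma = (G/s2 + A)^-1,  mu = Sigma F'y / s2
//   alpha_m <- (1 + 2a) / (mu_m^2 + Sigma_mm + 2b)
//   s2      <- (||y - F mu||^2 + s2 * sum_m gamma_m) / M,
//              gamma_m = 1 - alpha_m Sigma_mm
// Breakpoints with alpha above alpha_max or |mu| below w_floor are pruned.

static inline double u_of(double m, double M) {
  return std::sqrt(m / (M - m));
}

// [[Rcpp::export(name = ".sbl_core_cpp")]]
List sbl_core_cpp(NumericVector y, double a, double b,
                  int max_iter, double tol,
                  double alpha_max, double w_floor,
                  double sigma2_init) {
  const int M = y.size();
  if (M < 2) stop("need at least 2 probes");
  const double Md = (double)M;

  // center y (the constant basis component is the probe mean)
  double ybar = 0.0;
  for (int i = 0; i < M; ++i) ybar += y[i];
  ybar /= Md;
  std::vector<double> yc(M);
  double ss_y = 0.0;
  for (int i = 0; i < M; ++i) { yc[i] = y[i] - ybar; ss_y += yc[i] * yc[i]; }

  // z_m = f_m' y = -S_m * sqrt(M / (m (M - m))),  S_m = cumsum(yc);
  // the prefix sums also give every segment sum in O(1), keeping each
  // sweep O(k) (residual included)
  std::vector<double> z(M - 1), cumS(M + 1, 0.0);
  {
    double S = 0.0;
    for (int m = 1; m <= M; ++m) {
      S += yc[m - 1];
      cumS[m] = S;
      if (m <= M - 1)
        z[m - 1] = -S * std::sqrt(Md / ((double)m * (Md - (double)m)));
    }
  }

  // active set: 1-based breakpoint positions (jump after probe idx)
  std::vector<int> idx(M - 1);
  for (int m = 0; m < M - 1; ++m) idx[m] = m + 1;
  std::vector<double> alpha(M - 1, 1.0), mu(M - 1, 0.0);

  double s2 = sigma2_init;
  if (!(s2 > 0.0)) {
    // robust init from first differences (MAD-based)
    std::vector<double> d(M - 1);
    for (int i = 0; i < M - 1; ++i) d[i] = std::fabs(yc[i + 1] - yc[i]);
    std::nth_element(d.begin(), d.begin() + (M - 1) / 2, d.end());
    double med = d[(M - 1) / 2];
    double sd = med / (0.6744898 * std::sqrt(2.0));
    s2 = std::max(sd * sd, 1e-12);
  }

  bool converged = false;
  int iter = 0;

  std::vector<double> rho, Pd, Pe, v, dd, ee, rhs, t, cp, delta, gam,
      Sid, Sie, Sig, seg_val;

  for (iter = 1; iter <= max_iter; ++iter) {
    int k = (int)idx.size();
    if (k == 0) { s2 = ss_y / Md; converged = true; break; }

    rho.assign(std::max(k - 1, 0), 0.0);
    for (int c = 0; c + 1 < k; ++c)
      rho[c] = u_of((double)idx[c], Md) / u_of((double)idx[c + 1], Md);

    // tridiagonal inverse of the restricted Gram matrix (closed form)
    Pd.assign(k, 0.0); Pe.assign(std::max(k - 1, 0), 0.0);
    for (int c = 0; c < k; ++c) {
      double left  = (c > 0)     ? 1.0 / (1.0 - rho[c - 1] * rho[c - 1]) : 1.0;
      double right = (c < k - 1) ? 1.0 / (1.0 - rho[c] * rho[c])         : 1.0;
      Pd[c] = left + right - 1.0;
    }
    for (int c = 0; c + 1 < k; ++c)
      Pe[c] = -rho[c] / (1.0 - rho[c] * rho[c]);

    // v = P z_I
    v.assign(k, 0.0);
    for (int c = 0; c < k; ++c) {
      double s = Pd[c] * z[idx[c] - 1];
      if (c > 0)     s += Pe[c - 1] * z[idx[c - 1] - 1];
      if (c < k - 1) s += Pe[c]     * z[idx[c + 1] - 1];
      v[c] = s;
    }

    // symmetric tridiagonal S' = I + s2 * A^{1/2} P A^{1/2}
    dd.assign(k, 0.0); ee.assign(std::max(k - 1, 0), 0.0);
    for (int c = 0; c < k; ++c) dd[c] = 1.0 + s2 * alpha[c] * Pd[c];
    for (int c = 0; c + 1 < k; ++c)
      ee[c] = s2 * std::sqrt(alpha[c] * alpha[c + 1]) * Pe[c];

    // Thomas solve S' t = A^{1/2} v  ->  mu = A^{-1/2} t
    rhs.assign(k, 0.0);
    for (int c = 0; c < k; ++c) rhs[c] = std::sqrt(alpha[c]) * v[c];
    t.assign(k, 0.0); cp.assign(std::max(k - 1, 0), 0.0);
    {
      double piv = dd[0];
      t[0] = rhs[0] / piv;
      if (k > 1) cp[0] = ee[0] / piv;
      for (int c = 1; c < k; ++c) {
        piv = dd[c] - ee[c - 1] * cp[c - 1];
        t[c] = (rhs[c] - ee[c - 1] * t[c - 1]) / piv;
        if (c < k - 1) cp[c] = ee[c] / piv;
      }
      for (int c = k - 2; c >= 0; --c) t[c] -= cp[c] * t[c + 1];
    }
    mu.assign(k, 0.0);
    for (int c = 0; c < k; ++c) mu[c] = t[c] / std::sqrt(alpha[c]);

    // selected inverse of S' (diagonal + first off-diagonal)
    delta.assign(k, 0.0); gam.assign(k, 0.0);
    delta[0] = dd[0];
    for (int c = 1; c < k; ++c)
      delta[c] = dd[c] - ee[c - 1] * ee[c - 1] / delta[c - 1];
    gam[k - 1] = dd[k - 1];
    for (int c = k - 2; c >= 0; --c)
      gam[c] = dd[c] - ee[c] * ee[c] / gam[c + 1];
    Sid.assign(k, 0.0); Sie.assign(std::max(k - 1, 0), 0.0);
    for (int c = 0; c < k; ++c) Sid[c] = 1.0 / (delta[c] + gam[c] - dd[c]);
    for (int c = k - 2; c >= 0; --c)
      Sie[c] = -ee[c] * Sid[c + 1] / delta[c];

    // Sigma_cc = s2 * [ P A^{1/2} S'^{-1} A^{-1/2} ]_cc
    Sig.assign(k, 0.0);
    for (int c = 0; c < k; ++c) {
      double s = Pd[c] * Sid[c];
      if (c > 0)
        s += Pe[c - 1] * std::sqrt(alpha[c - 1] / alpha[c]) * Sie[c - 1];
      if (c < k - 1)
        s += Pe[c] * std::sqrt(alpha[c + 1] / alpha[c]) * Sie[c];
      Sig[c] = s2 * s;
      if (Sig[c] < 1e-300) Sig[c] = 1e-300;  // SPD in exact arithmetic
    }

    // residual of the piecewise-constant reconstruction
    seg_val.assign(k + 1, 0.0);
    {
      // suffix sums of a(idx)*mu, prefix sums of b(idx)*mu
      double suf = 0.0;
      for (int c = k - 1; c >= 0; --c) {
        double m = (double)idx[c];
        suf += -std::sqrt((Md - m) / (Md * m)) * mu[c];
        seg_val[c] = suf;  // partial: prefix part added next
      }
      seg_val[k] = 0.0;
      double pre = 0.0;
      for (int c = 0; c < k; ++c) {
        double m = (double)idx[c];
        // segment s has prefix over c' < s
        seg_val[c] += pre;
        pre += std::sqrt(m / (Md * (Md - m))) * mu[c];
      }
      seg_val[k] += pre;
    }
    double res2 = ss_y;
    for (int s = 0; s <= k; ++s) {
      int lo = (s == 0) ? 0 : idx[s - 1];
      int hi = (s == k) ? M : idx[s];
      double seg_sum = cumS[hi] - cumS[lo];
      res2 += seg_val[s] * (seg_val[s] * (double)(hi - lo) - 2.0 * seg_sum);
    }
    if (res2 < 0.0) res2 = 0.0;

    double sum_gamma = 0.0;
    for (int c = 0; c < k; ++c) sum_gamma += 1.0 - alpha[c] * Sig[c];
    double s2_new = (res2 + s2 * sum_gamma) / Md;
    if (s2_new < 1e-12) s2_new = 1e-12;

    // hyperparameter update + pruning
    std::vector<int> keep;
    keep.reserve(k);
    double max_rel = 0.0;
    std::vector<double> alpha_new(k);
    for (int c = 0; c < k; ++c) {
      alpha_new[c] = (1.0 + 2.0 * a) / (mu[c] * mu[c] + Sig[c] + 2.0 * b);
      if (alpha_new[c] < alpha_max && std::fabs(mu[c]) >= w_floor)
        keep.push_back(c);
    }
    for (size_t j = 0; j < keep.size(); ++j) {
      int c = keep[j];
      double rel = std::fabs(alpha_new[c] - alpha[c]) / alpha[c];
      if (rel > max_rel) max_rel = rel;
    }
    bool pruned = ((int)keep.size() < k);
    std::vector<int> idx2; idx2.reserve(keep.size());
    std::vector<double> al2, mu2;
    al2.reserve(keep.size()); mu2.reserve(keep.size());
    for (size_t j = 0; j < keep.size(); ++j) {
      idx2.push_back(idx[keep[j]]);
      al2.push_back(alpha_new[keep[j]]);
      mu2.push_back(mu[keep[j]]);
    }
    idx.swap(idx2); alpha.swap(al2); mu.swap(mu2);
    s2 = s2_new;

    if (!pruned && max_rel < tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  return List::create(
      _["breakpoints"] = wrap(idx),
      _["w"] = wrap(mu),
      _["alpha"] = wrap(alpha),
      _["sigma2"] = s2,
      _["n_iter"] = iter,
      _["converged"] = converged,
      _["mean"] = ybar);
}

// Gram-matrix inverse (tridiagonal, closed form) for an active breakpoint
// set; returned as diagonal and superdiagonal.  Shared by the t-statistic
// and backward-elimination code on the R side.
// [[Rcpp::export(name = ".bkp_gram_inv_cpp")]]
List bkp_gram_inv_cpp(IntegerVector idx, int M) {
  const int k = idx.size();
  const double Md = (double)M;
  NumericVector Pd(k), Pe(std::max(k - 1, 0));
  std::vector<double> rho(std::max(k - 1, 0));
  for (int c = 0; c + 1 < k; ++c)
    rho[c] = u_of((double)idx[c], Md) / u_of((double)idx[c + 1], Md);
  for (int c = 0; c < k; ++c) {
    double left  = (c > 0)     ? 1.0 / (1.0 - rho[c - 1] * rho[c - 1]) : 1.0;
    double right = (c < k - 1) ? 1.0 / (1.0 - rho[c] * rho[c])         : 1.0;
    Pd[c] = left + right - 1.0;
  }
  for (int c = 0; c + 1 < k; ++c) Pe[c] = -rho[c] / (1.0 - rho[c] * rho[c]);
  return List::create(_["diag"] = Pd, _["offdiag"] = Pe);
}
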