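// Forward-filter backward-sample for the companion-form AR(p) latent state
// observed through heteroscedastic Gaussian pseudo-observations (one scalar
// observation per bin, selector H = (1, 0, ..., 0), rank-1 innovation
// covariance Q = diag(sigma2, 0, ..., 0)).
//
// The backward step exploits the degeneracy of the companion transition:
// conditioning on X_{n+1} fixes components 1..p-1 of X_n exactly (they are
// lags of x carried inside X_{n+1}) and leaves a single scalar, the oldest
// lag, to be drawn. This is the rank-1 (Sherman-Morrison) form; the dense
// textbook step (A = V F' (F V F' + Q)^{-1}) is retained for cross-checking.
//
// The per-bin loops are hand-rolled on raw arrays: the sampler visits every
// (trial, bin) cell once per Gibbs iteration, so allocation-free O(p^2)
// updates are what keep desk-scale fits in minutes.
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// in-place Cholesky (lower) of SPD A (n x n, row-major); returns false on
// loss of positive definiteness
static bool chol_lower(double* A, int n) {
  for (int j = 0; j < n; ++j) {
    double d = A[j * n + j];
    for (int k = 0; k < j; ++k) d -= A[j * n + k] * A[j * n + k];
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    A[j * n + j] = d;
    for (int i = j + 1; i < n; ++i) {
      double s = A[i * n + j];
      for (int k = 0; k < j; ++k) s -= A[i * n + k] * A[j * n + k];
      A[i * n + j] = s / d;
    }
  }
  return true;
}

// solve L L' x = b given lower-triangular L (row-major), in place on b
static void chol_solve(const double* L, double* b, int n) {
  for (int i = 0; i < n; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * n + k] * b[k];
    b[i] = s / L[i * n + i];
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < n; ++k) s -= L[k * n + i] * b[k];
    b[i] = s / L[i * n + i];
  }
}

// forward Kalman pass; fm (p x N) and fc (p*p x N) column-major per bin
static void forward_filter_raw(const double* t, const double* r, int N,
                               const double* Fc, int p, double sigma2,
                               double v0, double* fm, double* fc,
                               double* filt_var1) {
  std::vector<double> m(p, 0.0), V(p * p, 0.0), pm(p), PV(p * p), FV(p);
  for (int i = 0; i < p; ++i) V[i * p + i] = v0;
  for (int n = 0; n < N; ++n) {
    // prediction mean
    double acc = 0.0;
    for (int i = 0; i < p; ++i) acc += Fc[i] * m[i];
    pm[0] = acc;
    for (int i = 1; i < p; ++i) pm[i] = m[i - 1];
    // FV = V * Fc
    for (int i = 0; i < p; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += V[i * p + j] * Fc[j];
      FV[i] = s;
    }
    double q00 = sigma2;
    for (int i = 0; i < p; ++i) q00 += Fc[i] * FV[i];
    PV[0] = q00;
    for (int j = 1; j < p; ++j) { PV[j] = FV[j - 1]; PV[j * p] = FV[j - 1]; }
    for (int i = 1; i < p; ++i)
      for (int j = 1; j < p; ++j) PV[i * p + j] = V[(i - 1) * p + (j - 1)];
    // scalar observation update
    double denom = PV[0] + r[n];
    double innov = t[n] - pm[0];
    for (int i = 0; i < p; ++i) m[i] = pm[i] + PV[i * p] / denom * innov;
    for (int i = 0; i < p; ++i) {
      double ki = PV[i * p] / denom;
      for (int j = 0; j < p; ++j) V[i * p + j] = PV[i * p + j] - ki * PV[j * p];
    }
    // symmetrize
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j) {
        double s = 0.5 * (V[i * p + j] + V[j * p + i]);
        V[i * p + j] = s; V[j * p + i] = s;
      }
    for (int i = 0; i < p; ++i) fm[n * p + i] = m[i];
    for (int k = 0; k < p * p; ++k) fc[n * (p * p) + k] = V[k];
    filt_var1[n] = V[0];
  }
}

static arma::vec mvn_draw(const arma::vec& m, const arma::mat& V) {
  int p = m.n_elem;
  arma::vec ev; arma::mat evec;
  arma::eig_sym(ev, evec, 0.5 * (V + V.t()));
  arma::vec z(p);
  for (int i = 0; i < p; ++i) z[i] = R::norm_rand();
  arma::vec s = arma::sqrt(arma::clamp(ev, 0.0, arma::datum::inf));
  return m + evec * (s % z);
}

// [[Rcpp::export(name = ".ffbs_trial")]]
List ffbs_trial_cpp(NumericVector t_, NumericVector r_, NumericVector Fc_,
                    double sigma2, double v0, bool dense, bool deterministic) {
  int N = t_.size(), p = Fc_.size();
  const double* Fc = Fc_.begin();
  NumericVector xout(N), X0out(p);
  std::vector<double> X((size_t)N * p), X0(p);

  if (dense) {
    // reference path: full filter storage, textbook backward gain
    std::vector<double> fm((size_t)N * p), fc((size_t)N * p * p), fv(N);
    forward_filter_raw(t_.begin(), r_.begin(), N, Fc, p, sigma2, v0,
                       fm.data(), fc.data(), fv.data());
    arma::mat F(p, p, arma::fill::zeros);
    for (int j = 0; j < p; ++j) F(0, j) = Fc[j];
    for (int i = 1; i < p; ++i) F(i, i - 1) = 1.0;
    {
      arma::vec m(p); arma::mat V(p, p);
      for (int i = 0; i < p; ++i) m[i] = fm[(size_t)(N - 1) * p + i];
      for (int i = 0; i < p; ++i)
        for (int j = 0; j < p; ++j) V(i, j) = fc[(size_t)(N - 1) * p * p + i * p + j];
      arma::vec d = deterministic ? m : mvn_draw(m, V);
      for (int i = 0; i < p; ++i) X[(size_t)(N - 1) * p + i] = d[i];
    }
    std::vector<double> m_prior(p, 0.0), V_prior((size_t)p * p, 0.0);
    for (int i = 0; i < p; ++i) V_prior[i * p + i] = v0;
    for (int n = N - 2; n >= -1; --n) {
      const double* m = (n >= 0) ? &fm[(size_t)n * p] : m_prior.data();
      const double* V = (n >= 0) ? &fc[(size_t)n * p * p] : V_prior.data();
      const double* xn1 = &X[(size_t)(n + 1) * p];
      double* x = (n >= 0) ? &X[(size_t)n * p] : X0.data();
      arma::vec ma(p), xv(p);
      arma::mat Va(p, p);
      for (int i = 0; i < p; ++i) {
        ma[i] = m[i]; xv[i] = xn1[i];
        for (int j = 0; j < p; ++j) Va(i, j) = V[i * p + j];
      }
      arma::mat S = F * Va * F.t();
      S(0, 0) += sigma2;
      arma::mat A = Va * F.t() * arma::inv(0.5 * (S + S.t()));
      arma::vec mean = ma + A * (xv - F * ma);
      arma::mat C = (arma::eye(p, p) - A * F) * Va;
      arma::vec d = deterministic ? mean : mvn_draw(mean, C);
      for (int i = 0; i < p; ++i) x[i] = d[i];
    }
    for (int n = 0; n < N; ++n) xout[n] = X[(size_t)n * p];
    for (int i = 0; i < p; ++i) X0out[i] = X0[i];
    NumericVector fvout(fv.begin(), fv.end());
    return List::create(_["x"] = xout, _["X0"] = X0out, _["filt_var1"] = fvout);
  }

  // rank-1 path: the backward conditional for the oldest lag of X_n given
  // the rest of X_n (known from X_{n+1}) and the next innovation needs only
  // the filter mean, alpha = B^{-1} v (B, v blocks of the filter covariance)
  // and the conditional variance -- all computable during the forward pass,
  // so the backward sweep is a handful of multiplies per bin.
  int q = p - 1;
  std::vector<double> m(p, 0.0), V((size_t)p * p, 0.0), pm(p), PV((size_t)p * p), FV(p);
  std::vector<double> fm((size_t)N * p), fal((size_t)N * (q > 0 ? q : 1)),
      fvc(N), fv(N), B((size_t)(q > 0 ? q * q : 1));
  std::vector<double> lastV((size_t)p * p);
  for (int i = 0; i < p; ++i) V[i * p + i] = v0;
  for (int n = 0; n < N; ++n) {
    double acc = 0.0;
    for (int i = 0; i < p; ++i) acc += Fc[i] * m[i];
    pm[0] = acc;
    for (int i = 1; i < p; ++i) pm[i] = m[i - 1];
    for (int i = 0; i < p; ++i) {
      double sx = 0.0;
      for (int j = 0; j < p; ++j) sx += V[i * p + j] * Fc[j];
      FV[i] = sx;
    }
    double q00 = sigma2;
    for (int i = 0; i < p; ++i) q00 += Fc[i] * FV[i];
    PV[0] = q00;
    for (int j = 1; j < p; ++j) { PV[j] = FV[j - 1]; PV[j * p] = FV[j - 1]; }
    for (int i = 1; i < p; ++i)
      for (int j = 1; j < p; ++j) PV[i * p + j] = V[(i - 1) * p + (j - 1)];
    double denom = PV[0] + r_[n];
    double innov = t_[n] - pm[0];
    for (int i = 0; i < p; ++i) m[i] = pm[i] + PV[i * p] / denom * innov;
    for (int i = 0; i < p; ++i) {
      double ki = PV[i * p] / denom;
      for (int j = 0; j < p; ++j) V[i * p + j] = PV[i * p + j] - ki * PV[j * p];
    }
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j) {
        double sx = 0.5 * (V[i * p + j] + V[j * p + i]);
        V[i * p + j] = sx; V[j * p + i] = sx;
      }
    fv[n] = V[0];
    for (int i = 0; i < p; ++i) fm[(size_t)n * p + i] = m[i];
    if (q > 0) {
      double dmax = 0.0;
      for (int i = 0; i < q; ++i) if (V[i * p + i] > dmax) dmax = V[i * p + i];
      double ridge = 1e-10 * (dmax > 0.0 ? dmax : 1.0);
      for (int i = 0; i < q; ++i)
        for (int j = 0; j < q; ++j)
          B[i * q + j] = V[i * p + j] + (i == j ? ridge : 0.0);
      double* al = &fal[(size_t)n * q];
      for (int i = 0; i < q; ++i) al[i] = V[i * p + q];
      if (chol_lower(B.data(), q)) {
        chol_solve(B.data(), al, q);
      } else {
        arma::mat Ba(q, q); arma::vec va(q);
        for (int i = 0; i < q; ++i) {
          va[i] = V[i * p + q];
          for (int j = 0; j < q; ++j) Ba(i, j) = V[i * p + j];
        }
        arma::vec sol = arma::solve(Ba + 1e-6 * (dmax > 0 ? dmax : 1.0) *
                                      arma::eye(q, q), va);
        for (int i = 0; i < q; ++i) al[i] = sol[i];
      }
      double vc = V[q * p + q];
      for (int i = 0; i < q; ++i) vc -= al[i] * V[i * p + q];
      fvc[n] = (vc < 1e-14) ? 1e-14 : vc;
    } else {
      fvc[n] = V[0];
    }
    if (n == N - 1)
      for (int k = 0; k < p * p; ++k) lastV[k] = V[k];
  }

  {
    arma::vec mv(p); arma::mat Va(p, p);
    for (int i = 0; i < p; ++i) {
      mv[i] = fm[(size_t)(N - 1) * p + i];
      for (int j = 0; j < p; ++j) Va(i, j) = lastV[i * p + j];
    }
    arma::vec d = deterministic ? mv : mvn_draw(mv, Va);
    for (int i = 0; i < p; ++i) X[(size_t)(N - 1) * p + i] = d[i];
  }

  std::vector<double> m_prior(p, 0.0), al_prior((size_t)(q > 0 ? q : 1), 0.0);
  for (int n = N - 2; n >= -1; --n) {
    const double* mn = (n >= 0) ? &fm[(size_t)n * p] : m_prior.data();
    const double* al = (n >= 0) ? &fal[(size_t)n * q] : al_prior.data();
    double var_c = (n >= 0) ? fvc[n] : v0;
    const double* xn1 = &X[(size_t)(n + 1) * p];
    double* x = (n >= 0) ? &X[(size_t)n * p] : X0.data();
    double mu_c, resid = xn1[0];
    if (p == 1) {
      mu_c = mn[0];
    } else {
      mu_c = mn[q];
      for (int i = 0; i < q; ++i) {
        x[i] = xn1[i + 1];
        mu_c += al[i] * (x[i] - mn[i]);
        resid -= Fc[i] * x[i];
      }
    }
    double Fp = Fc[p - 1];
    double prec = 1.0 / var_c + Fp * Fp / sigma2;
    double mean = (mu_c / var_c + Fp * resid / sigma2) / prec;
    double draw = deterministic ? mean : mean + R::norm_rand() / std::sqrt(prec);
    x[p - 1] = draw;
    if (p == 1) x[0] = draw;
  }

  for (int n = 0; n < N; ++n) xout[n] = X[(size_t)n * p];
  for (int i = 0; i < p; ++i) X0out[i] = X0[i];
  NumericVector fvout(fv.begin(), fv.end());
  return List::create(_["x"] = xout, _["X0"] = X0out, _["filt_var1"] = fvout);
}

// Moments of the backward-sampling density for one step, by both routes.
// [[Rcpp::export(name = ".backward_step_moments")]]
List backward_step_moments_cpp(NumericVector m_, NumericMatrix V_,
                               NumericVector xnext_, NumericVector Fc_,
                               double sigma2) {
  arma::vec m(m_.begin(), m_.size()), xn1(xnext_.begin(), xnext_.size()),
      Fc(Fc_.begin(), Fc_.size());
  arma::mat V(V_.begin(), V_.nrow(), V_.ncol());
  int p = Fc.n_elem;
  arma::mat F(p, p, arma::fill::zeros);
  F.row(0) = Fc.t();
  for (int i = 1; i < p; ++i) F(i, i - 1) = 1.0;

  arma::mat S = F * V * F.t();
  S(0, 0) += sigma2;
  arma::mat A = V * F.t() * arma::inv(0.5 * (S + S.t()));
  arma::vec mean_d = m + A * (xn1 - F * m);
  arma::mat cov_d = (arma::eye(p, p) - A * F) * V;

  arma::vec mean_r(p);
  arma::mat cov_r(p, p, arma::fill::zeros);
  double mu_c, var_c;
  if (p == 1) {
    mu_c = m[0]; var_c = V(0, 0);
  } else {
    arma::vec k = xn1.subvec(1, p - 1);
    mean_r.subvec(0, p - 2) = k;
    arma::mat B = V.submat(0, 0, p - 2, p - 2);
    arma::vec v = V.submat(0, p - 1, p - 2, p - 1);
    arma::vec alpha = arma::solve(0.5 * (B + B.t()), v);
    mu_c = m[p - 1] + arma::dot(alpha, k - m.subvec(0, p - 2));
    var_c = V(p - 1, p - 1) - arma::dot(alpha, v);
  }
  double Fp = Fc[p - 1];
  double resid = xn1[0];
  for (int i = 0; i < p - 1; ++i) resid -= Fc[i] * mean_r[i];
  double prec = 1.0 / var_c + Fp * Fp / sigma2;
  mean_r[p - 1] = (mu_c / var_c + Fp * resid / sigma2) / prec;
  cov_r(p - 1, p - 1) = 1.0 / prec;

  return List::create(_["mean_dense"] = wrap(mean_d), _["cov_dense"] = wrap(cov_d),
                      _["mean_rank1"] = wrap(mean_r), _["cov_rank1"] = wrap(cov_r));
}

// [[Rcpp::export(name = ".kalman_forward")]]
List kalman_forward_cpp(NumericVector t_, NumericVector r_, NumericVector Fc_,
                        double sigma2, double v0) {
  int N = t_.size(), p = Fc_.size();
  std::vector<double> fm((size_t)N * p), fc((size_t)N * p * p), fv(N);
  forward_filter_raw(t_.begin(), r_.begin(), N, Fc_.begin(), p, sigma2, v0,
                     fm.data(), fc.data(), fv.data());
  arma::mat FM(p, N);
  arma::cube FC(p, p, N);
  for (int n = 0; n < N; ++n) {
    for (int i = 0; i < p; ++i) FM(i, n) = fm[(size_t)n * p + i];
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) FC(i, j, n) = fc[(size_t)n * p * p + i * p + j];
  }
  return List::create(_["mean"] = wrap(FM), _["cov"] = wrap(FC));
}

// Marginal log-likelihood of one trial's pseudo-observations under the
// AR(p) prior with observation model t_n = s * x_n + N(0, r_n): Kalman
// prediction-error decomposition. Used by the collapsed class-indicator
// update of the mixture extension.
// [[Rcpp::export(name = ".kalman_loglik")]]
double kalman_loglik_cpp(NumericVector t_, NumericVector r_, NumericVector Fc_,
                         double sigma2, double v0, double sobs) {
  int N = t_.size(), p = Fc_.size();
  const double* t = t_.begin();
  const double* r = r_.begin();
  const double* Fc = Fc_.begin();
  std::vector<double> m(p, 0.0), V((size_t)p * p, 0.0), pm(p), PV((size_t)p * p), FV(p);
  for (int i = 0; i < p; ++i) V[i * p + i] = v0;
  double ll = 0.0;
  for (int n = 0; n < N; ++n) {
    double acc = 0.0;
    for (int i = 0; i < p; ++i) acc += Fc[i] * m[i];
    pm[0] = acc;
    for (int i = 1; i < p; ++i) pm[i] = m[i - 1];
    for (int i = 0; i < p; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += V[i * p + j] * Fc[j];
      FV[i] = s;
    }
    double q00 = sigma2;
    for (int i = 0; i < p; ++i) q00 += Fc[i] * FV[i];
    PV[0] = q00;
    for (int j = 1; j < p; ++j) { PV[j] = FV[j - 1]; PV[j * p] = FV[j - 1]; }
    for (int i = 1; i < p; ++i)
      for (int j = 1; j < p; ++j) PV[i * p + j] = V[(i - 1) * p + (j - 1)];
    double S = sobs * sobs * PV[0] + r[n];
    double e = t[n] - sobs * pm[0];
    ll += -0.5 * (std::log(2.0 * M_PI * S) + e * e / S);
    for (int i = 0; i < p; ++i) {
      double ki = sobs * PV[i * p] / S;
      m[i] = pm[i] + ki * e;
      for (int j = 0; j < p; ++j)
        V[i * p + j] = PV[i * p + j] - ki * sobs * PV[j * p];
    }
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j) {
        double s = 0.5 * (V[i * p + j] + V[j * p + i]);
        V[i * p + j] = s; V[j * p + i] = s;
      }
  }
  return ll;
}
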