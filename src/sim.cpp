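#include <Rcpp.h>
using namespace Rcpp;

// Last-spike lag map: l(m,n) = n - L(m,n), L(m,n) the index of the last
// spike strictly before bin n. 0 where the trial has no earlier spike.
// [[Rcpp::export(name = ".last_spike_lag")]]
IntegerMatrix last_spike_lag_cpp(IntegerMatrix y) {
  int M = y.nrow(), N = y.ncol();
  IntegerMatrix l(M, N);
  for (int m = 0; m < M; ++m) {
    int last = -1;
    for (int n = 0; n < N; ++n) {
      l(m, n) = (last < 0) ? 0 : n - last;
      if (y(m, n) == 1) last = n;
    }
  }
  return l;
}

// Inhomogeneous renewal spiking: spike at (m,n) iff U < dt*exp(mu_m + drive_mn
// + lambdaG[l(m,n)]). lambdaG indexed by lag in bins (1-based); 0 beyond its
// support and before the first spike of a trial. Probabilities > 1 are clipped
// (count and max reported).
// [[Rcpp::export(name = ".sim_renewal")]]
List sim_renewal_cpp(NumericMatrix drive, NumericVector mu, NumericVector lambdaG,
                     double dt) {
  int M = drive.nrow(), N = drive.ncol(), L = lambdaG.size();
  IntegerMatrix y(M, N);
  int nclip = 0;
  double pmax = 0.0;
  for (int m = 0; m < M; ++m) {
    int last = -1;
    for (int n = 0; n < N; ++n) {
      double lg = 0.0;
      if (last >= 0) {
        int lag = n - last;
        if (lag >= 1 && lag <= L) lg = lambdaG[lag - 1];
      }
      double p = (lg == R_NegInf) ? 0.0 : dt * std::exp(mu[m] + drive(m, n) + lg);
      if (p > pmax) pmax = p;
      if (p > 1.0) { p = 1.0; ++nclip; }
      if (R::unif_rand() < p) { y(m, n) = 1; last = n; }
    }
  }
  return List::create(_["y"] = y, _["n_clipped"] = nclip, _["max_p"] = pmax);
}

// Leaky integrate-and-fire with Euler integration:
//   dV = (-V/tau + f_n + mu_m + w_mn) dt + sigma_b sqrt(dt) z,  z ~ N(0,1)
// threshold 1, reset 0.
// [[Rcpp::export(name = ".sim_lif")]]
IntegerMatrix sim_lif_cpp(NumericMatrix w, NumericVector f, NumericVector mu,
                          double tau, double sigma_b, double dt) {
  int M = w.nrow(), N = w.ncol();
  IntegerMatrix y(M, N);
  double sq = sigma_b * std::sqrt(dt);
  for (int m = 0; m < M; ++m) {
    double V = 0.0;
    for (int n = 0; n < N; ++n) {
      double noise = (sq > 0.0) ? sq * R::norm_rand() : 0.0;
      V += (-V / tau + f[n] + mu[m] + w(m, n)) * dt + noise;
      if (V >= 1.0) { y(m, n) = 1; V = 0.0; }
    }
  }
  return y;
}

// Per-trial FIR filter: out[m, n] = sum_k a[k] * x[m, n - k], valid region
// only (n = q .. N-1, 0-based), so out has N - q columns.
// [[Rcpp::export(name = ".fir_filter")]]
NumericMatrix fir_filter_cpp(NumericMatrix x, NumericVector a) {
  int M = x.nrow(), N = x.ncol(), q = a.size() - 1;
  if (N <= q) stop("series shorter than filter");
  NumericMatrix out(M, N - q);
  const double* xp = x.begin();   // column-major
  double* op = out.begin();
  const double* ap = a.begin();
  for (int n = q; n < N; ++n) {
    double* oc = op + (size_t)(n - q) * M;
    for (int k = 0; k <= q; ++k) {
      const double* xc = xp + (size_t)(n - k) * M;
      double ak = ap[k];
      if (k == 0) {
        for (int m = 0; m < M; ++m) oc[m] = ak * xc[m];
      } else {
        for (int m = 0; m < M; ++m) oc[m] += ak * xc[m];
      }
    }
  }
  return out;
}

// pooled lag-regression sufficient statistics across trial rows:
// lag-2: y = w[, 3:K], d1 = w[, 2:(K-1)], d2 = w[, 1:(K-2)]
// returns (S11, S12, S22, Sy1, Sy2)
// [[Rcpp::export(name = ".lag2_stats")]]
NumericVector lag2_stats_cpp(NumericMatrix w) {
  int M = w.nrow(), K = w.ncol();
  const double* wp = w.begin();
  double S11 = 0, S12 = 0, S22 = 0, Sy1 = 0, Sy2 = 0;
  for (int n = 2; n < K; ++n) {
    const double* cy = wp + (size_t)n * M;
    const double* c1 = wp + (size_t)(n - 1) * M;
    const double* c2 = wp + (size_t)(n - 2) * M;
    for (int m = 0; m < M; ++m) {
      S11 += c1[m] * c1[m];
      S12 += c1[m] * c2[m];
      S22 += c2[m] * c2[m];
      Sy1 += cy[m] * c1[m];
      Sy2 += cy[m] * c2[m];
    }
  }
  return NumericVector::create(S11, S12, S22, Sy1, Sy2);
}

// lag-1: returns (Sxx, Sxy) with x = u[, 1:(K-1)], y = u[, 2:K]
// [[Rcpp::export(name = ".lag1_stats")]]
NumericVector lag1_stats_cpp(NumericMatrix u) {
  int M = u.nrow(), K = u.ncol();
  const double* up = u.begin();
  double Sxx = 0, Sxy = 0;
  for (int n = 1; n < K; ++n) {
    const double* cy = up + (size_t)n * M;
    const double* cx = up + (size_t)(n - 1) * M;
    for (int m = 0; m < M; ++m) {
      Sxx += cx[m] * cx[m];
      Sxy += cy[m] * cx[m];
    }
  }
  return NumericVector::create(Sxx, Sxy);
}
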