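#include <Rcpp.h>
using namespace Rcpp;

// Polya-Gamma PG(1, z) sampler: alternating-series rejection on the
// Jacobi J*(1, z/2) density (Devroye-style), X = J*/4. Uses R's RNG so
// draws are reproducible under set.seed().

static const double TRUNC = 0.64;

// n-th coefficient of the alternating series for the J*(1,.) density at x
static inline double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > TRUNC) {
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * 0.5 * x);
  } else {
    return M_PI * np5 * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * np5 * np5 / x);
  }
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC)
static double rtigauss(double z) {
  double x = TRUNC + 1.0;
  if (z < 1.0 / TRUNC) {
    // mu > TRUNC: rejection from scaled chi-square proposal
    double alpha = 0.0;
    while (R::runif(0.0, 1.0) > alpha) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC);
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > TRUNC) {
      double y = R::norm_rand();
      y = y * y;
      double half = mu * 0.5 * (mu * y - std::sqrt(4.0 * mu * y + mu * mu * y * y));
      x = mu + half;
      if (R::runif(0.0, 1.0) > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

static double rpg1_devroye(double z) {
  z = 0.5 * std::fabs(z);
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double b = std::sqrt(1.0 / TRUNC) * (TRUNC * z - 1.0);
  double a = -std::sqrt(1.0 / TRUNC) * (TRUNC * z + 1.0);
  double x0 = std::log(fz) + fz * TRUNC;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  double ratio = 1.0 / (1.0 + qdivp);

  for (;;) {
    double x;
    if (R::runif(0.0, 1.0) < ratio) {
      x = TRUNC + R::exp_rand() / fz;
    } else {
      x = rtigauss(z);
    }
    // squeeze via the alternating partial sums
    double s = a_coef(0, x);
    double y = R::runif(0.0, 1.0) * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break;  // reject, draw a new proposal
      }
    }
  }
}

// [[Rcpp::export(name = ".rpg_devroye")]]
NumericVector rpg_devroye_cpp(NumericVector psi) {
  R_xlen_t n = psi.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double z = psi[i];
    if (!R_finite(z)) stop("non-finite tilting argument at index %d", (int)(i + 1));
    out[i] = rpg1_devroye(z);
  }
  return out;
}
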