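// Exact Polya-gamma PG(1, z) sampler, Devroye-style alternating-series
// rejection following Polson, Scott & Windle (2013). A PG(1, z) variate is
// J*(1, z/2) / 4, where J* is the tilted Jacobi-type variable; the proposal
// mixes a truncated inverse-Gaussian left piece on (0, t] with an
// exponential right tail on (t, inf), t = 0.64. Uses R's RNG so draws are
// reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;

// Piecewise coefficients a_n(x) of the Jacobi density series.
static double a_coef(int n, double x) {
  double nph = n + 0.5;
  if (x <= TRUNC) {
    return M_PI * nph * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * nph * nph / x);
  }
  return M_PI * nph * std::exp(-nph * nph * M_PI * M_PI * x / 2.0);
}

// Inverse-Gaussian(mu, lambda = 1) CDF at x; mu = 1/z (z = 0 handled by the
// Levy limit 2 * Phi(-1/sqrt(x))).
static double pigauss(double x, double z) {
  if (z <= 0.0) return 2.0 * R::pnorm(-1.0 / std::sqrt(x), 0.0, 1.0, 1, 0);
  double rx = std::sqrt(x);
  double b = 1.0 / rx;
  return R::pnorm(rx * z - b, 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(-rx * z - b, 0.0, 1.0, 1, 0);
}

// Inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, t].
static double rtigauss(double z) {
  double t = TRUNC;
  double x = t + 1.0;
  if (1.0 / z > t) {
    // small tilt: sample 1/chi^2 truncated via double exponentials, then
    // thin by the Gaussian tilt exp(-z^2 x / 2)
    for (;;) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  // mu <= t: plain IG sampler (Michael-Schucany-Haas), reject until <= t
  double mu = 1.0 / z;
  while (x > t) {
    double y = R::norm_rand();
    y = y * y;
    double muy = mu * y;
    x = mu + 0.5 * mu * muy -
        0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
    if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
  }
  return x;
}

// One draw of PG(1, c).
static double rpg1_one(double c) {
  double z = std::fabs(c) * 0.5;  // J*(1, z) tilt
  double t = TRUNC;
  double K = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double p = (0.5 * M_PI / K) * std::exp(-K * t);
  double q = 2.0 * std::exp(-z) * pigauss(t, z);
  for (;;) {
    double x;
    if (R::unif_rand() < p / (p + q)) {
      x = t + R::exp_rand() / K;          // exponential right tail
    } else {
      x = rtigauss(z);                    // truncated IG left piece
    }
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;      // accept
      } else {
        s += a_coef(n, x);
        if (y > s) break;                 // reject, redraw x
      }
    }
  }
}

// [[Rcpp::export(name = ".rpg1")]]
NumericVector rpg1_cpp(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1_one(z[i]);
  return out;
}
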