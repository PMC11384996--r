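// Wiener diffusion core: first-passage-time density, trajectory simulation,
// and the robust (contaminant-mixture) negative log-likelihood.
//
// Geometry: the process starts at 0 with absorbing boundaries at +B and -B,
// drift mu (evidence/s) and diffusion coefficient sigma (evidence/sqrt(s)).
// Rescaling by sigma gives a unit-noise process with boundary separation
// a = 2B/sigma, relative start w = 1/2 and drift v = mu/sigma, for which the
// classic dual series expansions of the density apply.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

const double SERIES_EPS = 1e-12; // absolute truncation error of f0

// Density of the normalised first-passage time at the LOWER boundary for a
// zero-drift unit process with boundary separation 1 and relative start w,
// evaluated at normalised time tt = t / a^2.  Small-time and large-time
// series are switched where their truncation-term counts cross.
double f0(double tt, double w) {
  if (tt <= 0.0) return 0.0;

  // terms needed for the small-time representation
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * SERIES_EPS < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt *
                         std::log(2.0 * SERIES_EPS * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  // terms needed for the large-time representation
  double kl;
  if (M_PI * tt * SERIES_EPS < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * SERIES_EPS) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }

  double p = 0.0;
  if (ks < kl) { // small-time series
    int K = (int)std::ceil(ks);
    for (int k = -((K - 1) / 2); k <= ((K - 1) / 2) + 1; ++k) {
      double z = w + 2.0 * k;
      p += z * std::exp(-z * z / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {       // large-time series
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return std::max(p, 0.0);
}

// Defective FPT density at one boundary, in original units, at decision time
// td = t - t0 (already offset by the caller).
double wfpt_one(double td, double mu, double B, double sigma, bool upper) {
  if (td <= 0.0 || !R_finite(td)) return 0.0;
  double v = mu / sigma;
  double a = 2.0 * B / sigma;
  if (upper) v = -v;          // reflection symmetry at w = 1/2
  const double w = 0.5;
  double tt = td / (a * a);
  double scale = std::exp(-v * a * w - v * v * td / 2.0) / (a * a);
  return f0(tt, w) * scale;
}

} // namespace

// [[Rcpp::export(name = ".wfpt_cpp")]]
NumericVector wfpt_cpp(NumericVector t, double mu, double B, double t0,
                       double sigma, bool upper) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (!R_finite(t[i])) stop("non-finite time passed to the FPT density");
    out[i] = wfpt_one(t[i] - t0, mu, B, sigma, upper);
  }
  return out;
}

// Robust likelihood: per trial, (1 - lambda) * f(rt) + lambda / (2 (t_max - t0)).
// Parameter vectors are per-trial (recycled scalars are expanded in R).
// [[Rcpp::export(name = ".robust_nll_cpp")]]
double robust_nll_cpp(NumericVector rt, LogicalVector upper,
                      NumericVector mu, NumericVector B, NumericVector t0,
                      double sigma, double lambda, double t_max) {
  int n = rt.size();
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double f = wfpt_one(rt[i] - t0[i], mu[i], B[i], sigma, upper[i] != 0);
    double span = t_max - t0[i];
    double lik = (1.0 - lambda) * f;
    if (lambda > 0.0 && span > 0.0) lik += lambda / (2.0 * span);
    if (lik <= 0.0) return R_PosInf;
    nll -= std::log(lik);
  }
  return nll;
}

// Euler-Maruyama simulation with per-trial parameters.  Uses the R RNG so
// that set.seed() governs reproducibility.  Returns a 2-column matrix:
// column 1 = choice (1 upper, 0 lower, NA no absorption by t_max),
// column 2 = RT in seconds (t0 + crossing time; NA for non-response).
// With probability lambda a trial is a contaminant: uniform RT on
// (t0, t_max) with a fair-coin boundary.
// [[Rcpp::export(name = ".sim_ddm_cpp")]]
NumericMatrix sim_ddm_cpp(NumericVector mu, NumericVector B, NumericVector t0,
                          double sigma, double lambda, double t_max, double dt) {
  if (dt <= 0.0) stop("dt must be positive");
  int n = mu.size();
  NumericMatrix out(n, 2);
  RNGScope scope;
  double sq = sigma * std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    if (lambda > 0.0 && unif_rand() < lambda) {
      out(i, 0) = (unif_rand() < 0.5) ? 1.0 : 0.0;
      out(i, 1) = t0[i] + unif_rand() * (t_max - t0[i]);
      continue;
    }
    double x = 0.0, td = 0.0;
    double horizon = t_max - t0[i];
    bool absorbed = false;
    double var = sigma * sigma * dt;
    while (td < horizon) {
      double xp = x;
      x += mu[i] * dt + sq * norm_rand();
      td += dt;
      if (x >= B[i]) { out(i, 0) = 1.0; absorbed = true; break; }
      if (x <= -B[i]) { out(i, 0) = 0.0; absorbed = true; break; }
      // Brownian-bridge probability that the continuous path touched a
      // boundary inside the step; removes the O(sqrt(dt)) absorption bias
      // of the plain Euler scheme.
      double p_up = std::exp(-2.0 * (B[i] - xp) * (B[i] - x) / var);
      if (unif_rand() < p_up) { out(i, 0) = 1.0; absorbed = true; break; }
      double p_lo = std::exp(-2.0 * (B[i] + xp) * (B[i] + x) / var);
      if (unif_rand() < p_lo) { out(i, 0) = 0.0; absorbed = true; break; }
    }
    if (absorbed && t0[i] + td <= t_max) {
      out(i, 1) = t0[i] + td;
    } else {
      out(i, 0) = NA_REAL;
      out(i, 1) = NA_REAL;
    }
  }
  return out;
}
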