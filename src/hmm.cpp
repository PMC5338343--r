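#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Fractional bound-state occupancy of each camera frame given an alternating
// continuous-time dwell sequence.  Frame i integrates [i*dt, (i+1)*dt); the
// dwell list starts at t = 0 and must cover at least n_frames*dt seconds.
// [[Rcpp::export]]
NumericVector frame_occupancy_cpp(NumericVector durations, bool first_bound,
                                  int n_frames, double dt) {
  NumericVector occ(n_frames);
  const double total = n_frames * dt;
  double t0 = 0.0;
  bool bound = first_bound;
  for (R_xlen_t d = 0; d < durations.size(); ++d) {
    const double t1 = t0 + durations[d];
    if (bound) {
      const double a = t0;
      const double b = std::min(t1, total);
      if (b > a) {
        int i0 = (int)std::floor(a / dt);
        int i1 = (int)std::ceil(b / dt);
        if (i0 < 0) i0 = 0;
        if (i1 > n_frames) i1 = n_frames;
        for (int i = i0; i < i1; ++i) {
          const double lo = std::max(a, i * dt);
          const double hi = std::min(b, (i + 1) * dt);
          if (hi > lo) occ[i] += (hi - lo) / dt;
        }
      }
    }
    t0 = t1;
    bound = !bound;
    if (t0 >= total) break;
  }
  return occ;
}

static inline double gauss_pdf(double x, double mu, double sd) {
  const double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

// Two-state Gaussian hidden Markov model fitted by Baum-Welch (scaled
// forward-backward) with the most probable path recovered by Viterbi.
// Initialisation is a deterministic two-way intensity split, so repeated
// fits of the same trace are identical.  States are in internal order
// (0 = lower initial mean); relabelling by emission mean happens in R.
// [[Rcpp::export]]
List fit_hmm2_cpp(NumericVector y, int max_iter, double tol) {
  const int T = y.size();
  double ymin = R_PosInf, ymax = R_NegInf;
  for (int t = 0; t < T; ++t) {
    if (y[t] < ymin) ymin = y[t];
    if (y[t] > ymax) ymax = y[t];
  }
  const double rng = ymax - ymin;
  if (!(rng > 0)) {
    // constant trace: no information to separate two states
    return List::create(_["states"] = IntegerVector(T),
                        _["mu"] = NumericVector::create(ymin, ymin),
                        _["sd"] = NumericVector::create(0.0, 0.0),
                        _["loglik"] = NA_REAL, _["iterations"] = 0,
                        _["converged"] = true, _["degenerate"] = true);
  }
  const double sd_floor = std::max(1e-6 * rng, 1e-300);

  // deterministic split halfway between the 5% and 95% quantiles
  std::vector<double> ys(y.begin(), y.end());
  std::sort(ys.begin(), ys.end());
  const double q05 = ys[(size_t)std::floor(0.05 * (T - 1))];
  const double q95 = ys[(size_t)std::floor(0.95 * (T - 1))];
  double thr = 0.5 * (q05 + q95);
  int n0 = 0;
  for (int t = 0; t < T; ++t) if (y[t] <= thr) ++n0;
  if (n0 == 0 || n0 == T) {  // fall back to a median split
    thr = ys[T / 2];
    n0 = 0;
    for (int t = 0; t < T; ++t) if (y[t] <= thr) ++n0;
    if (n0 == 0 || n0 == T) n0 = std::max(1, T / 2);
  }

  double mu[2] = {0.0, 0.0}, sd[2] = {0.0, 0.0};
  {
    double s0 = 0, s1 = 0, ss0 = 0, ss1 = 0;
    int c0 = 0, c1 = 0;
    for (int t = 0; t < T; ++t) {
      if (y[t] <= thr && c0 < n0) { s0 += y[t]; ++c0; }
      else { s1 += y[t]; ++c1; }
    }
    if (c0 == 0) { c0 = 1; s0 = ymin; --c1; s1 -= 0; }
    if (c1 == 0) { c1 = 1; s1 = ymax; }
    mu[0] = s0 / c0; mu[1] = s1 / c1;
    for (int t = 0; t < T; ++t) {
      if (y[t] <= thr) ss0 += (y[t] - mu[0]) * (y[t] - mu[0]);
      else ss1 += (y[t] - mu[1]) * (y[t] - mu[1]);
    }
    sd[0] = std::max(std::sqrt(ss0 / std::max(c0, 1)), sd_floor);
    sd[1] = std::max(std::sqrt(ss1 / std::max(c1, 1)), sd_floor);
  }
  double A[2][2] = {{0.95, 0.05}, {0.05, 0.95}};
  double pi0[2] = {(double)n0 / T, 1.0 - (double)n0 / T};
  if (pi0[0] <= 0) pi0[0] = 1e-6;
  if (pi0[1] <= 0) pi0[1] = 1e-6;

  std::vector<double> alpha(2 * T), beta(2 * T), gam(2 * T), scale(T), b(2 * T);
  double loglik = R_NegInf;
  int iter = 0;
  bool converged = false;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int t = 0; t < T; ++t) {
      double b0 = gauss_pdf(y[t], mu[0], sd[0]);
      double b1 = gauss_pdf(y[t], mu[1], sd[1]);
      if (b0 <= 0 && b1 <= 0) { b0 = b1 = 1e-300; }
      b[2 * t] = std::max(b0, 1e-300);
      b[2 * t + 1] = std::max(b1, 1e-300);
    }
    // scaled forward
    double a0 = pi0[0] * b[0], a1 = pi0[1] * b[1];
    double c = a0 + a1;
    scale[0] = c;
    alpha[0] = a0 / c; alpha[1] = a1 / c;
    for (int t = 1; t < T; ++t) {
      a0 = (alpha[2 * (t - 1)] * A[0][0] + alpha[2 * (t - 1) + 1] * A[1][0]) * b[2 * t];
      a1 = (alpha[2 * (t - 1)] * A[0][1] + alpha[2 * (t - 1) + 1] * A[1][1]) * b[2 * t + 1];
      c = a0 + a1;
      if (c <= 0) c = 1e-300;
      scale[t] = c;
      alpha[2 * t] = a0 / c; alpha[2 * t + 1] = a1 / c;
    }
    double ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(scale[t]);

    // scaled backward
    beta[2 * (T - 1)] = 1.0; beta[2 * (T - 1) + 1] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      const double bb0 = b[2 * (t + 1)] * beta[2 * (t + 1)];
      const double bb1 = b[2 * (t + 1) + 1] * beta[2 * (t + 1) + 1];
      beta[2 * t] = (A[0][0] * bb0 + A[0][1] * bb1) / scale[t + 1];
      beta[2 * t + 1] = (A[1][0] * bb0 + A[1][1] * bb1) / scale[t + 1];
    }
    // posteriors and expected transition counts
    double xi[2][2] = {{0, 0}, {0, 0}};
    for (int t = 0; t < T; ++t) {
      double g0 = alpha[2 * t] * beta[2 * t];
      double g1 = alpha[2 * t + 1] * beta[2 * t + 1];
      const double gs = g0 + g1;
      gam[2 * t] = g0 / gs; gam[2 * t + 1] = g1 / gs;
      if (t < T - 1) {
        for (int i = 0; i < 2; ++i)
          for (int j = 0; j < 2; ++j)
            xi[i][j] += alpha[2 * t + i] * A[i][j] * b[2 * (t + 1) + j] *
                        beta[2 * (t + 1) + j] / scale[t + 1];
      }
    }
    // M-step
    pi0[0] = gam[0]; pi0[1] = gam[1];
    for (int i = 0; i < 2; ++i) {
      const double denom = xi[i][0] + xi[i][1];
      if (denom > 0) {
        A[i][0] = std::min(std::max(xi[i][0] / denom, 1e-8), 1.0 - 1e-8);
        A[i][1] = 1.0 - A[i][0];
      }
    }
    for (int j = 0; j < 2; ++j) {
      double w = 0, wx = 0;
      for (int t = 0; t < T; ++t) { w += gam[2 * t + j]; wx += gam[2 * t + j] * y[t]; }
      if (w > 1e-10) {
        mu[j] = wx / w;
        double wss = 0;
        for (int t = 0; t < T; ++t)
          wss += gam[2 * t + j] * (y[t] - mu[j]) * (y[t] - mu[j]);
        sd[j] = std::max(std::sqrt(wss / w), sd_floor);
      }
    }
    if (iter > 1 && std::fabs(ll - loglik) < tol * (1.0 + std::fabs(ll))) {
      loglik = ll;
      converged = true;
      break;
    }
    loglik = ll;
  }

  // Viterbi (log space)
  std::vector<double> delta(2 * T);
  std::vector<int> psi(2 * T);
  const double lA[2][2] = {{std::log(A[0][0]), std::log(A[0][1])},
                           {std::log(A[1][0]), std::log(A[1][1])}};
  for (int j = 0; j < 2; ++j) {
    const double bj = std::max(gauss_pdf(y[0], mu[j], sd[j]), 1e-300);
    delta[j] = std::log(std::max(pi0[j], 1e-300)) + std::log(bj);
  }
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < 2; ++j) {
      const double p0 = delta[2 * (t - 1)] + lA[0][j];
      const double p1 = delta[2 * (t - 1) + 1] + lA[1][j];
      const int from = (p1 > p0) ? 1 : 0;
      const double bj = std::max(gauss_pdf(y[t], mu[j], sd[j]), 1e-300);
      delta[2 * t + j] = ((from == 0) ? p0 : p1) + std::log(bj);
      psi[2 * t + j] = from;
    }
  }
  IntegerVector states(T);
  states[T - 1] = (delta[2 * (T - 1) + 1] > delta[2 * (T - 1)]) ? 1 : 0;
  for (int t = T - 2; t >= 0; --t) states[t] = psi[2 * (t + 1) + states[t + 1]];

  return List::create(_["states"] = states,
                      _["mu"] = NumericVector::create(mu[0], mu[1]),
                      _["sd"] = NumericVector::create(sd[0], sd[1]),
                      _["loglik"] = loglik, _["iterations"] = iter,
                      _["converged"] = converged, _["degenerate"] = false);
}
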