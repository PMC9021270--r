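#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// xoshiro256++ (public-domain construction) seeded through splitmix64;
// fast, high-quality stream independent of R's RNG so that integer
// seeds reproduce trajectories bitwise across platforms.
struct Xoshiro256pp {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xBF58476D1CE4E5B9ULL;
      t = (t ^ (t >> 27)) * 0x94D049BB133111EBULL;
      s[i] = t ^ (t >> 31);
    }
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0,1)
};

// Standard normals via Box-Muller with pair caching.
struct NormalGen {
  Xoshiro256pp rng;
  bool have = false;
  double cached = 0.0;
  explicit NormalGen(uint64_t seed) : rng(seed) {}
  inline double operator()() {
    if (have) { have = false; return cached; }
    double u1;
    do { u1 = rng.unif(); } while (u1 <= 0.0);
    double u2 = rng.unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925 * u2;
    cached = r * std::sin(a);
    have = true;
    return r * std::cos(a);
  }
};

// Sigmoidal F-I curve x / (1 - exp(-d x)) with x = m g (I - I_thr).
// Near x = 0 the expression has a removable singularity with limit 1/d;
// a short series keeps it smooth to machine precision.
static inline double fi_curve(double x, double d) {
  double y = d * x;
  if (std::fabs(y) < 1e-6) {
    return (1.0 / d) / (1.0 - 0.5 * y + y * y / 6.0);
  }
  return x / (1.0 - std::exp(-y));
}

// Euler-Maruyama integration of the two-population dynamic mean field
// model. Time is in ms throughout; rates are Hz and enter the gating
// drift in kHz (r/1000) so that tau values stay in ms. The excitatory
// rate trace is bin-averaged every `record_ms` after discarding
// `burn_ms`. State is (S_E, S_I) per region, clipped to [0,1].
// [[Rcpp::export]]
List dmf_integrate_cpp(const NumericMatrix& C, double G,
                       const NumericVector& J, const NumericVector& gain,
                       const List& par, double dt, double duration_ms,
                       double burn_ms, double record_ms, int seed,
                       const NumericVector& s_e0, const NumericVector& s_i0,
                       bool return_trace) {
  const int n = C.nrow();
  if (C.ncol() != n) stop("coupling matrix must be square");
  if (J.size() != n || gain.size() != n)
    stop("J and gain must have one entry per region");

  const double I0      = as<double>(par["I0"]);
  const double W_E     = as<double>(par["W_E"]);
  const double W_I     = as<double>(par["W_I"]);
  const double w_plus  = as<double>(par["w_plus"]);
  const double J_NMDA  = as<double>(par["J_NMDA"]);
  const double g_E     = as<double>(par["g_E"]);
  const double g_I     = as<double>(par["g_I"]);
  const double I_thr_E = as<double>(par["I_thr_E"]);
  const double I_thr_I = as<double>(par["I_thr_I"]);
  const double d_E     = as<double>(par["d_E"]);
  const double d_I     = as<double>(par["d_I"]);
  const double gamma_k = as<double>(par["gamma"]);
  const double sigma   = as<double>(par["sigma"]);
  const double tau_E   = as<double>(par["tau_NMDA"]);
  const double tau_I   = as<double>(par["tau_GABA"]);

  const long n_steps    = (long)std::llround(duration_ms / dt);
  const long burn_steps = (long)std::llround(burn_ms / dt);
  const long rec_every  = std::max(1L, (long)std::llround(record_ms / dt));
  const long kept_steps = n_steps - burn_steps;
  if (kept_steps <= 0) stop("duration must exceed burn-in");
  const long n_rec = kept_steps / rec_every;

  std::vector<double> SE(n), SI(n), rE(n), acc(n, 0.0), sum_r(n, 0.0);
  for (int i = 0; i < n; ++i) { SE[i] = s_e0[i]; SI[i] = s_i0[i]; }

  NumericMatrix trace(return_trace ? n : 1, return_trace ? n_rec : 1);

  NormalGen nd((uint64_t)seed);
  const bool noisy = sigma > 0.0;

  // CSR view of the (symmetric) coupling matrix: connectomes are
  // typically sparse and the coupling matvec dominates the step cost.
  std::vector<int> row_ptr(n + 1, 0);
  std::vector<int> col_idx;
  std::vector<double> col_val;
  for (int i = 0; i < n; ++i) {
    const double* col = &C(0, i);
    for (int p = 0; p < n; ++p) {
      if (col[p] != 0.0) { col_idx.push_back(p); col_val.push_back(col[p]); }
    }
    row_ptr[i + 1] = (int)col_idx.size();
  }

  const double sq_dt = std::sqrt(dt);
  long rec_count = 0, in_bin = 0, kept = 0;

  std::vector<double> rI(n);
  for (long t = 0; t < n_steps; ++t) {
    // currents and rates from the state at the start of the step
    for (int i = 0; i < n; ++i) {
      double net = 0.0;
      for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
        net += col_val[k] * SE[col_idx[k]];
      double I_E = W_E * I0 + w_plus * J_NMDA * SE[i] +
                   G * J_NMDA * net - J[i] * SI[i];
      double I_I = W_I * I0 + J_NMDA * SE[i] - SI[i];
      rE[i] = fi_curve(g_E * (I_E - I_thr_E), d_E);
      rI[i] = fi_curve(gain[i] * g_I * (I_I - I_thr_I), d_I);
    }
    for (int i = 0; i < n; ++i) {
      double dSE = -SE[i] / tau_E + (1.0 - SE[i]) * gamma_k * rE[i] * 1e-3;
      double dSI = -SI[i] / tau_I + rI[i] * 1e-3;
      SE[i] += dt * dSE;
      SI[i] += dt * dSI;
      if (noisy) {
        SE[i] += sigma * sq_dt * nd();
        SI[i] += sigma * sq_dt * nd();
      }
      if (SE[i] < 0.0) SE[i] = 0.0; else if (SE[i] > 1.0) SE[i] = 1.0;
      if (SI[i] < 0.0) SI[i] = 0.0; else if (SI[i] > 1.0) SI[i] = 1.0;
    }
    if (!R_finite(SE[0])) {
      return List::create(_["ok"] = false, _["step"] = (double)t);
    }
    if (t >= burn_steps) {
      ++kept;
      for (int i = 0; i < n; ++i) { acc[i] += rE[i]; sum_r[i] += rE[i]; }
      if (++in_bin == rec_every) {
        if (return_trace && rec_count < n_rec) {
          for (int i = 0; i < n; ++i)
            trace(i, rec_count) = acc[i] / rec_every;
        }
        ++rec_count;
        in_bin = 0;
        std::fill(acc.begin(), acc.end(), 0.0);
      }
    }
  }

  NumericVector r_mean(n), se_out(n), si_out(n);
  for (int i = 0; i < n; ++i) {
    r_mean[i] = kept > 0 ? sum_r[i] / kept : NA_REAL;
    se_out[i] = SE[i];
    si_out[i] = SI[i];
  }
  bool finite_ok = true;
  for (int i = 0; i < n; ++i)
    if (!R_finite(SE[i]) || !R_finite(SI[i])) finite_ok = false;

  return List::create(_["ok"] = finite_ok,
                      _["r_mean"] = r_mean,
                      _["trace"] = return_trace ? (SEXP)trace : R_NilValue,
                      _["s_e"] = se_out, _["s_i"] = si_out,
                      _["n_recorded"] = (double)rec_count);
}

// Balloon-Windkessel haemodynamics, Euler-integrated at the resolution
// of the neural drive z (regions x time). State per region is
// (s, f, v, q) with resting fixed point (0, 1, 1, 1); BOLD is sampled
// once every `tr_steps` input samples.
// [[Rcpp::export]]
List bw_integrate_cpp(const NumericMatrix& z, double dt_s, int tr_steps,
                      double kappa, double gamma_h, double tau_h,
                      double alpha, double rho, double V0,
                      double k1, double k2, double k3) {
  const int n = z.nrow();
  const int T = z.ncol();
  const int n_tr = T / tr_steps;
  if (n_tr < 1) stop("neural drive shorter than one TR");
  NumericMatrix bold(n, n_tr);
  const double ia = 1.0 / alpha;

  for (int i = 0; i < n; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    int col = 0;
    for (int t = 0; t < T; ++t) {
      double zi = z(i, t);
      double vf = std::pow(v, ia);
      double E = 1.0 - std::pow(1.0 - rho, 1.0 / f);
      double ds = zi - kappa * s - gamma_h * (f - 1.0);
      double df = s;
      double dv = (f - vf) / tau_h;
      double dq = (f * E / rho - vf * q / v) / tau_h;
      s += dt_s * ds;
      f += dt_s * df;
      v += dt_s * dv;
      q += dt_s * dq;
      // inflow is physically positive; deep undershoots after strong
      // silent periods would otherwise push Euler's f through zero and
      // blow up the (1-rho)^(1/f) term
      if (f < 1e-4) f = 1e-4;
      if (!(v > 0.0) || !(q > 0.0) || !R_finite(q)) {
        return List::create(_["ok"] = false, _["step"] = (double)t,
                            _["region"] = i + 1);
      }
      if ((t + 1) % tr_steps == 0 && col < n_tr) {
        bold(i, col++) =
            V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
      }
    }
  }
  return List::create(_["ok"] = true, _["bold"] = bold);
}

// Two-sample Peacock-style 2-D Kolmogorov-Smirnov statistic on points
// (x, y): the maximum over all data points of both samples and all four
// quadrant orientations of the absolute difference between the two
// empirical quadrant CDFs.
// [[Rcpp::export]]
double ks2d_cpp(const NumericVector& x1, const NumericVector& y1,
                const NumericVector& x2, const NumericVector& y2) {
  const int n1 = x1.size(), n2 = x2.size();
  if (n1 == 0 || n2 == 0) stop("empty sample");
  double d_max = 0.0;
  auto scan = [&](double px, double py) {
    int a1 = 0, b1 = 0, c1 = 0;  // (<=,<=), (<=,>), (>,<=) for sample 1
    for (int k = 0; k < n1; ++k) {
      bool lx = x1[k] <= px, ly = y1[k] <= py;
      if (lx && ly) ++a1; else if (lx) ++b1; else if (ly) ++c1;
    }
    int a2 = 0, b2 = 0, c2 = 0;
    for (int k = 0; k < n2; ++k) {
      bool lx = x2[k] <= px, ly = y2[k] <= py;
      if (lx && ly) ++a2; else if (lx) ++b2; else if (ly) ++c2;
    }
    double f1, f2, d;
    f1 = (double)a1 / n1; f2 = (double)a2 / n2;
    d = std::fabs(f1 - f2); if (d > d_max) d_max = d;
    f1 = (double)b1 / n1; f2 = (double)b2 / n2;
    d = std::fabs(f1 - f2); if (d > d_max) d_max = d;
    f1 = (double)c1 / n1; f2 = (double)c2 / n2;
    d = std::fabs(f1 - f2); if (d > d_max) d_max = d;
    f1 = (double)(n1 - a1 - b1 - c1) / n1;
    f2 = (double)(n2 - a2 - b2 - c2) / n2;
    d = std::fabs(f1 - f2); if (d > d_max) d_max = d;
  };
  for (int k = 0; k < n1; ++k) scan(x1[k], y1[k]);
  for (int k = 0; k < n2; ++k) scan(x2[k], y2[k]);
  return d_max;
}
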