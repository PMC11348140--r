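#include <Rcpp.h>
using namespace Rcpp;

// xoshiro256++ with splitmix64 seeding: a fast, self-contained noise
// source for the integrators, deterministic in the 64-bit seed passed
// from R (independent of R's RNG kind).
struct XoshiroNorm {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;
  explicit XoshiroNorm(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {  // Marsaglia polar
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

// population transfer function (ax - b) / (1 - exp(-d (ax - b)));
// the removable singularity at a x = b evaluates to 1/d
static inline double hrate(double x, double a, double b, double d) {
  double u = a * x - b;
  if (std::fabs(u) < 1e-9) return 1.0 / d;
  return u / (1.0 - std::exp(-d * u));
}

// [[Rcpp::export(name = ".mfm_integrate_cpp")]]
NumericMatrix mfm_integrate_cpp(NumericMatrix C, NumericVector W,
                                NumericVector I, NumericVector sigma,
                                double G, double J, double a, double b,
                                double d, double tau_s, double gamma_k,
                                double dt, double duration,
                                int store_every, NumericVector S0,
                                double seed) {
  const int N = C.nrow();
  const int steps = (int)std::round(duration / dt);
  const int nstore = steps / store_every;
  NumericMatrix out(nstore, N);
  std::vector<double> S(N), x(N);
  for (int i = 0; i < N; ++i) S[i] = S0[i];
  XoshiroNorm rng((uint64_t)seed);
  const double sqdt = std::sqrt(dt);
  int row = 0;
  for (int t = 1; t <= steps; ++t) {
    // total input: recurrent + global coupling + external
    for (int i = 0; i < N; ++i) x[i] = W[i] * J * S[i] + I[i];
    for (int j = 0; j < N; ++j) {
      const double gjs = G * J * S[j];
      if (gjs != 0.0)
        for (int i = 0; i < N; ++i) x[i] += C(i, j) * gjs;
    }
    for (int i = 0; i < N; ++i) {
      double drift = -S[i] / tau_s + gamma_k * (1.0 - S[i]) * hrate(x[i], a, b, d);
      double Si = S[i] + drift * dt;
      if (sigma[i] > 0.0) Si += sigma[i] * sqdt * rng.norm();
      if (Si < 0.0) Si = 0.0;
      if (Si > 1.0) Si = 1.0;
      S[i] = Si;
    }
    if (t % store_every == 0 && row < nstore) {
      for (int i = 0; i < N; ++i) out(row, i) = S[i];
      ++row;
    }
  }
  return out;
}

// Balloon-Windkessel hemodynamics: neural drive -> BOLD, sampled at TR.
// [[Rcpp::export(name = ".balloon_bold_cpp")]]
NumericMatrix balloon_bold_cpp(NumericMatrix S, double dt, double TR,
                               double burn_in) {
  const int T = S.nrow(), N = S.ncol();
  const double kappa = 0.65, gam = 0.41, tau = 0.98, alpha = 0.32,
               rho = 0.34, V0 = 0.02;
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  const int per_tr = (int)std::round(TR / dt);
  const int skip = (int)std::round(burn_in / dt);
  const int nout = (T - skip) / per_tr;
  NumericMatrix out(nout, N);
  for (int i = 0; i < N; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    int row = 0;
    for (int t = 0; t < T; ++t) {
      double z = S(t, i);
      double fin = f > 1e-6 ? f : 1e-6;
      double E = 1.0 - std::pow(1.0 - rho, 1.0 / fin);
      double ds = z - kappa * s - gam * (f - 1.0);
      double df = s;
      double dv = (f - std::pow(v, 1.0 / alpha)) / tau;
      double dq = (f * E / rho - std::pow(v, 1.0 / alpha) * q / v) / tau;
      s += ds * dt; f += df * dt; v += dv * dt; q += dq * dt;
      if (v < 1e-6) v = 1e-6;
      if (q < 1e-6) q = 1e-6;
      if (f < 1e-6) f = 1e-6;
      if (t >= skip && ((t - skip + 1) % per_tr == 0) && row < nout) {
        out(row, i) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
        ++row;
      }
    }
  }
  return out;
}

// Fused integration + Balloon-Windkessel: returns BOLD at TR
// resolution directly, never materializing the gating trace.
// [[Rcpp::export(name = ".mfm_bold_cpp")]]
NumericMatrix mfm_bold_cpp(NumericMatrix C, NumericVector W,
                           NumericVector I, NumericVector sigma,
                           double G, double J, double a, double b,
                           double d, double tau_s, double gamma_k,
                           double dt, double duration, double TR,
                           double burn_in, NumericVector S0,
                           int hemo_every = 5, double seed = 1) {
  const int N = C.nrow();
  const int steps = (int)std::round(duration / dt);
  const int per_tr = (int)std::round(TR / dt);
  const int skip = (int)std::round(burn_in / dt);
  const int nout = (steps - skip) / per_tr;
  const double kappa = 0.65, gam = 0.41, tau = 0.98, alpha = 0.32,
               rho = 0.34, V0 = 0.02;
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  // hemodynamic state advances every `hemo_every` neural steps with the
  // mean gating over the window (balloon time constants ~1 s >> dt)
  const double dth = dt * hemo_every;
  NumericMatrix out(nout, N);
  std::vector<double> S(N), x(N), acc(N, 0.0),
      hs(N, 0.0), hf(N, 1.0), hv(N, 1.0), hq(N, 1.0);
  for (int i = 0; i < N; ++i) S[i] = S0[i];
  XoshiroNorm rng((uint64_t)seed);
  const double sqdt = std::sqrt(dt);
  const double *Cp = C.begin();
  int row = 0;
  for (int t = 1; t <= steps; ++t) {
    for (int i = 0; i < N; ++i) x[i] = W[i] * J * S[i] + I[i];
    for (int j = 0; j < N; ++j) {
      const double gjs = G * J * S[j];
      if (gjs != 0.0) {
        const double *cj = Cp + (size_t)j * N;
        for (int i = 0; i < N; ++i) x[i] += cj[i] * gjs;
      }
    }
    for (int i = 0; i < N; ++i) {
      double drift = -S[i] / tau_s + gamma_k * (1.0 - S[i]) * hrate(x[i], a, b, d);
      double Si = S[i] + drift * dt;
      if (sigma[i] > 0.0) Si += sigma[i] * sqdt * rng.norm();
      if (Si < 0.0) Si = 0.0;
      if (Si > 1.0) Si = 1.0;
      S[i] = Si;
      acc[i] += Si;
    }
    if (t % hemo_every == 0) {
      for (int i = 0; i < N; ++i) {
        double z = acc[i] / hemo_every;
        acc[i] = 0.0;
        double f = hf[i] > 1e-6 ? hf[i] : 1e-6;
        double E = 1.0 - std::pow(1.0 - rho, 1.0 / f);
        double vo = std::pow(hv[i], 1.0 / alpha);
        double ds = z - kappa * hs[i] - gam * (hf[i] - 1.0);
        double dv = (hf[i] - vo) / tau;
        double dq = (hf[i] * E / rho - vo * hq[i] / hv[i]) / tau;
        hs[i] += ds * dth; hf[i] += hs[i] * dth;
        hv[i] += dv * dth; hq[i] += dq * dth;
        if (hv[i] < 1e-6) hv[i] = 1e-6;
        if (hq[i] < 1e-6) hq[i] = 1e-6;
      }
    }
    if (t > skip && ((t - skip) % per_tr == 0) && row < nout) {
      for (int i = 0; i < N; ++i)
        out(row, i) = V0 * (k1 * (1.0 - hq[i]) + k2 * (1.0 - hq[i] / hv[i]) +
                            k3 * (1.0 - hv[i]));
      ++row;
    }
  }
  return out;
}
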