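// Three-population (deep ELL -> EGp -> superficial ELL) leaky integrate-and-fire
// network, Euler-Maruyama integration with delta synapses onto EGp and an
// exponentially filtered inhibitory projection onto the superficial pair.
//
// The hot loop draws ~1e3 normal variates per 0.05 ms step, so the simulator
// carries its own deterministic RNG (xoshiro256++ seeded via splitmix64, with a
// 128-layer ziggurat for normals) instead of going through R's RNG.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro256 {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    // avoid the all-zero state (cannot occur from splitmix64, but be safe)
    if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 1;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Marsaglia-Tsang ziggurat tables for the standard normal (128 layers).
struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];

  Ziggurat() {
    const double m1 = 2147483648.0;  // 2^31
    const double vn = 9.91256303526217e-3;
    double dn = 3.442619855899, tn = dn;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }

  inline double draw(Xoshiro256 &rng) const {
    for (;;) {
      uint64_t u = rng.next();
      int i = (int)(u & 127);
      int32_t j = (int32_t)(uint32_t)(u >> 32);
      double x = j * wn[i];
      if ((uint32_t)std::abs(j) < kn[i]) return x;
      if (i == 0) {  // tail
        const double r = 3.442619855899;
        double xx, yy;
        do {
          xx = -std::log(rng.unif()) / r;
          yy = -std::log(rng.unif());
        } while (yy + yy < xx * xx);
        return (j > 0) ? r + xx : -(r + xx);
      }
      if (fn[i] + rng.unif() * (fn[i - 1] - fn[i]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

const Ziggurat zig;

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_normals(double seed, int n) {
  Xoshiro256 rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = zig.draw(rng);
  return out;
}

// [[Rcpp::export]]
List sim_ell_cpp(List par, double duration, double dt, double burn_in,
                 int n_trials, double seed, double bin_width,
                 bool feedback_full) {
  const int N_D = as<int>(par["N_D"]);
  const int N_E = as<int>(par["N_E"]);
  const int N_S = as<int>(par["N_S"]);
  const double tau_D = as<double>(par["tau_D"]);
  const double tau_E = as<double>(par["tau_E"]);
  const double tau_S = as<double>(par["tau_S"]);
  const double mu_D = as<double>(par["mu_D"]);
  const double mu_E = as<double>(par["mu_E"]);
  const double mu_S = as<double>(par["mu_S"]);
  const double V_th = as<double>(par["V_th"]);
  const double V_r = as<double>(par["V_r"]);
  const double sigma = as<double>(par["sigma"]);
  const double g_A = as<double>(par["g_A"]);
  const double J_DE = as<double>(par["J_DE"]);
  const double J_ES0 = as<double>(par["J_ES"]);
  const double tau_syn = as<double>(par["tau_s"]);
  const double c_deep = as<double>(par["c_deep"]);
  const double c_sup = as<double>(par["c_sup"]);
  const double p_locked = as<double>(par["p_locked"]);
  const bool feedback_on = as<bool>(par["feedback_on"]);
  const double J_ES = feedback_on ? J_ES0 : 0.0;

  const long n_burn = (long)std::llround(burn_in / dt);
  const long n_rec = (long)std::llround(duration / dt);
  const long n_steps = n_burn + n_rec;
  const long bin_stride = std::max(1L, (long)std::llround(bin_width / dt));
  const long n_bins = n_rec / bin_stride;

  // Euler-Maruyama coefficients. Private noises of a neuron are combined into
  // a single draw; the shared stimulus term is a separate common draw.
  const double aD = dt / tau_D, aE = dt / tau_E, aS = dt / tau_S;
  const double nD_lock = std::sqrt(2.0 * dt / tau_D) *
                         std::sqrt(sigma * sigma + g_A * g_A * (1.0 - c_deep));
  const double nD_unlk = std::sqrt(2.0 * dt / tau_D) *
                         std::sqrt(sigma * sigma + g_A * g_A);
  const double cD = std::sqrt(2.0 * dt / tau_D) * g_A * std::sqrt(c_deep);
  const double nE = std::sqrt(2.0 * dt / tau_E) * sigma;
  const double nS = std::sqrt(2.0 * dt / tau_S) *
                    std::sqrt(sigma * sigma + g_A * g_A * (1.0 - c_sup));
  const double cS = std::sqrt(2.0 * dt / tau_S) * g_A * std::sqrt(c_sup);
  const double jump_DE = J_DE / (double)N_D;
  const double wfb = J_ES / (double)N_E;  // feedback weight per EGp neuron
  const double decay_syn = std::exp(-dt / tau_syn);

  // Brownian-bridge threshold correction: an excursion above threshold
  // within a step is spiking even if the endpoint lands below threshold;
  // P(cross) = exp(-2 (Vth - V0)(Vth - V1) / s2) with s2 the per-step
  // noise variance. Removes the dominant O(sqrt(dt)) rate bias of
  // endpoint-only threshold tests. Gated where P < ~1e-4.
  const double s2D_lock = nD_lock * nD_lock + cD * cD;
  const double s2D_unlk = nD_unlk * nD_unlk;
  const double s2E = nE * nE;
  const double s2S = nS * nS + cS * cS;

  const int n_lock = (int)std::lround(p_locked * N_D);

  // Stimulus RNG is shared across trials (frozen stimulus); the locked-subset
  // choice also derives from it so membership is a function of the seed only.
  Xoshiro256 stim_master((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<int> locked_id(N_D);
  for (int i = 0; i < N_D; ++i) locked_id[i] = i;
  {
    for (int i = 0; i < n_lock; ++i) {  // partial Fisher-Yates
      int j = i + (int)(stim_master.next() % (uint64_t)(N_D - i));
      std::swap(locked_id[i], locked_id[j]);
    }
  }
  // branch-free per-neuron coefficients for the deep update
  std::vector<double> noise_coef(N_D, nD_unlk), common_coef(N_D, 0.0),
      s2_coef(N_D, s2D_unlk);
  for (int i = 0; i < n_lock; ++i) {
    noise_coef[locked_id[i]] = nD_lock;
    common_coef[locked_id[i]] = cD;
    s2_coef[locked_id[i]] = s2D_lock;
  }
  const uint64_t stim_stream_seed = stim_master.next();

  List trials_D(n_trials), trials_E(n_trials), trials_S(n_trials);
  List fb_list(n_trials), stim_list(n_trials), fb_full_list(n_trials);

  const double inv_sqrt_dt = 1.0 / std::sqrt(dt);

  for (int trial = 0; trial < n_trials; ++trial) {
    Xoshiro256 stim_rng(stim_stream_seed);
    Xoshiro256 rng((uint64_t)seed + 0x9E3779B97F4A7C15ULL *
                                        (uint64_t)(trial + 1));

    std::vector<double> VD(N_D), VE(N_E), VS(N_S);
    for (int i = 0; i < N_D; ++i) VD[i] = V_r + (V_th - V_r) * rng.unif();
    for (int i = 0; i < N_E; ++i) VE[i] = V_r + (V_th - V_r) * rng.unif();
    for (int i = 0; i < N_S; ++i) VS[i] = V_r + (V_th - V_r) * rng.unif();

    std::vector<std::vector<double>> spkD(N_D), spkE(N_E), spkS(N_S);
    NumericVector stim_bin(n_bins), fb_bin(n_bins);
    NumericVector fb_full(feedback_full ? n_rec : 0);

    double syn = 0.0;  // pooled EGp spike train filtered by exp kernel, Hz
    bool bad = false;

    for (long step = 0; step < n_steps; ++step) {
      const double S = zig.draw(stim_rng);
      const bool rec = step >= n_burn;
      const double t = (step - n_burn) * dt;

      int nspkD = 0;
      for (int i = 0; i < N_D; ++i) {
        const double v0 = VD[i];
        double v = v0 + aD * (mu_D - v0) + zig.draw(rng) *
                       noise_coef[i] + common_coef[i] * S;
        bool spk = v >= V_th;
        if (!spk) {
          const double q = (V_th - v0) * (V_th - v);
          if (q < 4.5 * s2_coef[i])
            spk = rng.unif() < std::exp(-2.0 * q / s2_coef[i]);
        }
        if (spk) {
          ++nspkD;
          if (rec) spkD[i].push_back(t);
          v = V_r;
        }
        VD[i] = v;
      }

      int nspkE = 0;
      const double driveE = jump_DE * nspkD;
      for (int i = 0; i < N_E; ++i) {
        const double v0 = VE[i];
        double v = v0 + aE * (mu_E - v0) + driveE + nE * zig.draw(rng);
        bool spk = v >= V_th;
        if (!spk) {
          const double q = (V_th - v0) * (V_th - v);
          if (q < 4.5 * s2E)
            spk = rng.unif() < std::exp(-2.0 * q / s2E);
        }
        if (spk) {
          ++nspkE;
          if (rec) spkE[i].push_back(t);
          v = V_r;
        }
        VE[i] = v;
      }

      syn = syn * decay_syn + nspkE / tau_syn;
      const double fb_drive = wfb * syn;  // mV/s, summed over EGp population

      for (int i = 0; i < N_S; ++i) {
        const double v0 = VS[i];
        double v = v0 + aS * (mu_S - v0) + cS * S +
                   nS * zig.draw(rng) + dt * fb_drive;
        bool spk = v >= V_th;
        if (!spk) {
          const double q = (V_th - v0) * (V_th - v);
          if (q < 4.5 * s2S)
            spk = rng.unif() < std::exp(-2.0 * q / s2S);
        }
        if (spk) {
          if (rec) spkS[i].push_back(t);
          v = V_r;
        }
        VS[i] = v;
      }
      if (!std::isfinite(VS[0]) || !std::isfinite(VD[0])) {
        bad = true;
        break;
      }

      if (rec) {
        long b = (step - n_burn) / bin_stride;
        if (b < n_bins) {
          stim_bin[b] += S * inv_sqrt_dt / bin_stride;
          fb_bin[b] += fb_drive / bin_stride;
        }
        if (feedback_full) fb_full[step - n_burn] = fb_drive;
      }
    }
    if (bad)
      stop("membrane potential diverged (non-finite voltage): dt too large?");

    List lD(N_D), lE(N_E), lS(N_S);
    for (int i = 0; i < N_D; ++i) lD[i] = wrap(spkD[i]);
    for (int i = 0; i < N_E; ++i) lE[i] = wrap(spkE[i]);
    for (int i = 0; i < N_S; ++i) lS[i] = wrap(spkS[i]);
    trials_D[trial] = lD;
    trials_E[trial] = lE;
    trials_S[trial] = lS;
    stim_list[trial] = stim_bin;
    fb_list[trial] = fb_bin;
    if (feedback_full) fb_full_list[trial] = fb_full;
  }

  return List::create(
      _["deep"] = trials_D, _["egp"] = trials_E, _["superficial"] = trials_S,
      _["stimulus"] = stim_list, _["feedback"] = fb_list,
      _["feedback_full"] = fb_full_list,
      _["locked"] = IntegerVector(locked_id.begin(),
                                  locked_id.begin() + n_lock),
      _["n_bins"] = (double)n_bins, _["bin_width"] = bin_stride * dt,
      _["dt"] = dt, _["duration"] = n_rec * dt);
}
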