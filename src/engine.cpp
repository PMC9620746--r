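// Episode engine: spiking place-cell -> action-neuron network with
// reward-modulated STDP, integrated at a fixed step (default 1 ms).
//
// Dynamics use exact two-state exponential recursions for the
// double-exponential EPSP and rate-filter kernels; presynaptic spikes
// arriving at or before a postsynaptic spike are dropped from the sums
// by resetting the per-neuron accumulators (strict t > t_hat). STDP
// pairings feed lazily-scaled eligibility accumulators G with
// Gamma(t) = exp(-t/tau_e) * G(t), so no per-step decay of the full
// synapse matrices is needed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// splitmix64 (seeding) + xoshiro256+ (stream); deterministic per seed.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double u01() { return (next() >> 11) * 0x1.0p-53; }
};

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

} // namespace

// [[Rcpp::export(name = ".engine_episode")]]
List engine_episode(NumericMatrix w_feed_in, NumericMatrix centers,
                    double sigma, double peak_rate,
                    NumericMatrix w_lat, NumericVector theta, double a0,
                    List mem, double tau_gamma, double nu_gamma,
                    double dt, double dt_move, double t_max_ms,
                    NumericMatrix zones, NumericVector start,
                    double half_side, double d0,
                    int rule, List plast,
                    bool sequential_cwc, bool neutral_updates,
                    bool learning, double seed,
                    bool record_traj, bool record_spikes) {
  const int n_act = w_feed_in.nrow();
  const int n_pc  = w_feed_in.ncol();
  const double tau_m   = as<double>(mem["tau_m"]);
  const double tau_s   = as<double>(mem["tau_s"]);
  const double chi     = as<double>(mem["chi"]);
  const double eps0    = as<double>(mem["eps0"]);
  const double theta_u = as<double>(mem["theta"]);
  const double delta_u = as<double>(mem["delta_u"]);
  const double lambda0 = as<double>(mem["lambda0"]);

  const double ada      = as<double>(plast["ada"]);
  const double a5_base  = as<double>(plast["a5ht"]);
  const double mod_5ht  = as<double>(plast["mod_5ht"]);
  const double eta_da   = as<double>(plast["eta_da"]);
  const double eta_5ht  = as<double>(plast["eta_5ht"]);
  const double w_min    = as<double>(plast["w_min"]);
  const double w_max    = as<double>(plast["w_max"]);
  const double rda_amp  = as<double>(plast["rda_amp"]);
  const double r5_amp   = as<double>(plast["r5ht_amp"]);
  const double t_da_ms  = 1000.0 * as<double>(plast["t_da"]);
  const double da_delay = 1000.0 * as<double>(plast["da_delay"]);
  const double tau_stdp = as<double>(plast["tau_stdp"]);
  const double tau_e_da = 1000.0 * as<double>(plast["tau_e_da"]);
  const double tau_e_5  = 1000.0 * as<double>(plast["tau_e_5ht"]);

  const bool cwc_like  = (rule == 1 || rule == 4);
  const bool rate_mode = (rule == 3 || rule == 4);
  // SWC carries the optogenetic/ablation multiplier on the window
  // amplitude; CWC carries it on the modulator response amplitude.
  const double a5  = cwc_like ? a5_base : a5_base * mod_5ht;
  const double r5  = r5_amp * mod_5ht;

  const int n_steps    = (int) std::lround(t_max_ms / dt);
  const int move_every = (int) std::lround(dt_move / dt);
  const double dt_blk_s = dt_move / 1000.0;

  const double dm = std::exp(-dt / tau_m), dsyn = std::exp(-dt / tau_s);
  const double dgm = std::exp(-dt / tau_gamma), dgs = std::exp(-dt / nu_gamma);
  const double dstdp = std::exp(-dt / tau_stdp);
  const double kda = std::exp(dt / tau_e_da), k5 = std::exp(dt / tau_e_5);
  const double c_eps = eps0 / (tau_m - tau_s);
  const double rho_scale = 1000.0 / (tau_gamma - nu_gamma); // Hz per state diff

  std::vector<double> w(w_feed_in.begin(), w_feed_in.end()); // column-major (j + i*n_act)
  std::vector<double> Fm(n_act, 0), Fs(n_act, 0), Lm(n_act, 0), Ls(n_act, 0);
  std::vector<double> Gm(n_act, 0), Gs(n_act, 0), ytr(n_act, 0);
  std::vector<double> Ref(n_act, 0);     // refractory after-potential (mV)
  std::vector<double> xtr(n_pc, 0), lam_pc(n_pc, 0), p_pc(n_pc, 0);
  std::vector<int> last_spk(n_act, -1);
  std::vector<double> Gda(n_act * (size_t)n_pc, 0.0), G5(n_act * (size_t)n_pc, 0.0);
  std::vector<double> I5; // buffered integral of Gamma_5HT (ms units)
  const bool need_I5 = learning && (rule == 2 || (cwc_like && sequential_cwc));
  if (need_I5) I5.assign(n_act * (size_t)n_pc, 0.0);
  std::vector<double> sth(n_act), cth(n_act);
  for (int j = 0; j < n_act; ++j) { sth[j] = std::sin(theta[j]); cth[j] = std::cos(theta[j]); }

  std::vector<int> active;                 // place cells with non-negligible rate
  const double lam_min = 1e-3;             // Hz; below this a cell is silent
  const double cut2 = sigma * sigma * std::log(peak_rate / lam_min);

  double px = start[0], py = start[1];
  Xoshiro rng((uint64_t) seed);

  std::vector<double> traj_x, traj_y;
  if (record_traj) { traj_x.push_back(px); traj_y.push_back(py); }
  std::vector<double> sp_t_pre, sp_t_post;
  std::vector<int> sp_i_pre, sp_i_post;

  double esc_da = 1.0, esc_5 = 1.0;        // exp(t / tau_e)
  int outcome = 0;                          // 0 none, 1 reward, -1 punishment
  double t_out = t_max_ms;
  std::vector<int> curpre; curpre.reserve(16);
  std::vector<int> curpost; curpost.reserve(8);

  // refresh active place-cell set and rates for the current position
  auto refresh_rates = [&]() {
    active.clear();
    for (int i = 0; i < n_pc; ++i) {
      double dx = px - centers(i, 0), dy = py - centers(i, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < cut2) {
        lam_pc[i] = peak_rate * std::exp(-d2 / (sigma * sigma));
        p_pc[i] = lam_pc[i] * dt / 1000.0;
        active.push_back(i);
      } else {
        lam_pc[i] = 0.0; p_pc[i] = 0.0;
      }
    }
  };
  refresh_rates();

  int step = 0;
  for (step = 0; step < n_steps; ++step) {
    // ---- movement + block-level plasticity at block boundaries ----
    if (step > 0 && step % move_every == 0) {
      double ax = 0, ay = 0;
      for (int j = 0; j < n_act; ++j) {
        double rho = (Gm[j] - Gs[j]) * rho_scale;
        ax += rho * sth[j]; ay += rho * cth[j];
      }
      ax *= a0 / n_act; ay *= a0 / n_act;            // velocity, a.u./s
      double nx = px + ax * dt_blk_s, ny = py + ay * dt_blk_s;
      if (std::abs(nx) <= half_side && std::abs(ny) <= half_side) {
        px = nx; py = ny;
      } else {
        if (nx > half_side) px -= d0; else if (nx < -half_side) px += d0;
        if (ny > half_side) py -= d0; else if (ny < -half_side) py += d0;
        px = clampd(px, -half_side, half_side);
        py = clampd(py, -half_side, half_side);
      }
      if (record_traj) { traj_x.push_back(px); traj_y.push_back(py); }
      for (int z = 0; z < zones.nrow(); ++z) {
        double dx = px - zones(z, 0), dy = py - zones(z, 1);
        if (dx * dx + dy * dy <= zones(z, 2) * zones(z, 2)) {
          outcome = (int) zones(z, 3);
          break;
        }
      }
      if (outcome != 0) { t_out = step * dt; break; }
      refresh_rates();

      if (learning) {
        if (rate_mode) {
          // expected pairing rate nu_pre * nu_post * int W, via the traces
          const double wi_da = 2.0 * ada * tau_stdp / 1000.0;  // s
          const double wi_5  = a5 * tau_stdp / 1000.0;
          for (int j = 0; j < n_act; ++j) {
            double rho = (Gm[j] - Gs[j]) * rho_scale;
            if (rho <= 0) continue;
            double fda = wi_da * rho * dt_blk_s * esc_da;
            double f5  = wi_5 * rho * dt_blk_s * esc_5;
            for (size_t a = 0; a < active.size(); ++a) {
              int i = active[a];
              size_t idx = (size_t) j + (size_t) i * n_act;
              Gda[idx] += fda * lam_pc[i];
              G5[idx]  += f5 * lam_pc[i];
            }
          }
        }
        if (cwc_like && !sequential_cwc) {
          // tonic serotonergic depression while the episode runs
          double f = eta_da * r5 * dt_move / esc_5;
          if (f != 0) {
            for (size_t idx = 0; idx < G5.size(); ++idx) {
              double nw = w[idx] - f * G5[idx];
              w[idx] = clampd(nw, w_min, w_max);
            }
          }
        }
        if (need_I5) {
          double f = dt_move / esc_5;
          for (size_t idx = 0; idx < G5.size(); ++idx) I5[idx] += f * G5[idx];
        }
      }
    }

    // ---- per-millisecond neural dynamics ----
    for (int j = 0; j < n_act; ++j) {
      Fm[j] *= dm; Fs[j] *= dsyn; Lm[j] *= dm; Ls[j] *= dsyn;
      Gm[j] *= dgm; Gs[j] *= dgs; ytr[j] *= dstdp; Ref[j] *= dm;
    }
    for (int i = 0; i < n_pc; ++i) xtr[i] *= dstdp;
    esc_da *= kda; esc_5 *= k5;

    curpre.clear();
    for (size_t a = 0; a < active.size(); ++a) {
      int i = active[a];
      if (rng.u01() < p_pc[i]) {
        curpre.push_back(i);
        for (int j = 0; j < n_act; ++j) {
          double wj = w[(size_t) j + (size_t) i * n_act];
          Fm[j] += wj; Fs[j] += wj;
        }
        if (learning && !rate_mode) {
          // post-before-pre pairings (s < 0): only the symmetric DA window
          double f = ada * esc_da;
          for (int j = 0; j < n_act; ++j) {
            if (ytr[j] > 1e-12)
              Gda[(size_t) j + (size_t) i * n_act] += f * ytr[j];
          }
        }
        if (record_spikes) { sp_t_pre.push_back((step + 1) * dt); sp_i_pre.push_back(i + 1); }
      }
    }

    curpost.clear();
    double t_now = (step + 1) * dt;
    // below u_floor the emission probability is < ~1e-19 per step;
    // skip the exponential and the draw for those neurons
    const double u_floor = theta_u - 40.0 * delta_u;
    for (int j = 0; j < n_act; ++j) {
      double u = c_eps * (Fm[j] - Fs[j] + Lm[j] - Ls[j]) + Ref[j];
      if (u < u_floor) continue;
      double lam = lambda0 * std::exp((u - theta_u) / delta_u);
      double p = lam * dt / 1000.0;
      if (p > 1.0) p = 1.0;
      if (rng.u01() < p) curpost.push_back(j);
    }

    for (size_t c = 0; c < curpost.size(); ++c) {
      int j = curpost[c];
      if (learning && !rate_mode) {
        double fda = ada * esc_da, f5 = a5 * esc_5;
        for (int i = 0; i < n_pc; ++i) {
          double x = xtr[i];
          if (x > 1e-12) {
            size_t idx = (size_t) j + (size_t) i * n_act;
            Gda[idx] += fda * x;
            G5[idx]  += f5 * x;
          }
        }
        // coincident pre/post (s = 0): full DA amplitude, half 5-HT
        for (size_t a = 0; a < curpre.size(); ++a) {
          size_t idx = (size_t) j + (size_t) curpre[a] * n_act;
          Gda[idx] += fda;
          G5[idx]  += 0.5 * f5;
        }
      }
      Fm[j] = Fs[j] = Lm[j] = Ls[j] = 0.0;   // spikes at t <= t_hat drop out
      Ref[j] = chi;                          // decays by exp(-dt/tau_m) per step
      last_spk[j] = step;
      Gm[j] += 1.0; Gs[j] += 1.0;
      ytr[j] += 1.0;
      if (record_spikes) { sp_t_post.push_back(t_now); sp_i_post.push_back(j + 1); }
    }
    // lateral EPSPs from this step's spikes (excluded for neurons that
    // themselves spiked now: arrival time equals their t_hat)
    for (size_t c = 0; c < curpost.size(); ++c) {
      int k = curpost[c];
      for (int j = 0; j < n_act; ++j) {
        if (j == k) continue;
        bool self = false;
        for (size_t c2 = 0; c2 < curpost.size(); ++c2)
          if (curpost[c2] == j) { self = true; break; }
        if (self) continue;
        double wl = w_lat(j, k);
        Lm[j] += wl; Ls[j] += wl;
      }
    }
    for (size_t a = 0; a < curpre.size(); ++a) xtr[curpre[a]] += 1.0;
  }

  // ---- end-of-episode plasticity ----
  NumericMatrix dw_raw(n_act, n_pc); // unclipped terminal update (sequential rules)
  if (learning) {
    if (rule == 0 || rule == 2 || rule == 3) {
      // sequential: exactly one modulator resolves the episode
      if (outcome == 1) {
        double scale = eta_da * std::exp(-da_delay / tau_e_da) / esc_da;
        for (size_t idx = 0; idx < Gda.size(); ++idx) {
          double d = scale * Gda[idx];
          dw_raw[idx] = d;
          w[idx] = clampd(w[idx] + d, w_min, w_max);
        }
      } else if (outcome == -1 || neutral_updates) {
        if (rule == 2) {
          double scale = -eta_5ht / t_max_ms;
          for (size_t idx = 0; idx < G5.size(); ++idx) {
            double d = scale * I5[idx];
            dw_raw[idx] = d;
            w[idx] = clampd(w[idx] + d, w_min, w_max);
          }
        } else {
          double scale = -eta_5ht / esc_5;
          for (size_t idx = 0; idx < G5.size(); ++idx) {
            double d = scale * G5[idx];
            dw_raw[idx] = d;
            w[idx] = clampd(w[idx] + d, w_min, w_max);
          }
        }
      }
    } else { // cwc, rate-cwc
      if (sequential_cwc) {
        // outcome-gated commitment (open-field reversal): reward commits
        // the phasic DA integral, punishment the buffered 5-HT integral
        if (outcome == 1) {
          double gscale = 1.0 / esc_da;
          int nb = (int) std::lround(t_da_ms / dt_move);
          double dec = std::exp(-dt_move / tau_e_da);
          double g = gscale;
          for (int b = 0; b < nb; ++b) {
            g *= dec;
            double f = eta_da * rda_amp * g * dt_move;
            for (size_t idx = 0; idx < Gda.size(); ++idx) {
              double d = f * Gda[idx];
              dw_raw[idx] += d;
              w[idx] = clampd(w[idx] + d, w_min, w_max);
            }
          }
        } else if (outcome == -1) {
          double f = -eta_da * r5;
          for (size_t idx = 0; idx < G5.size(); ++idx) {
            double d = f * I5[idx];
            dw_raw[idx] = d;
            w[idx] = clampd(w[idx] + d, w_min, w_max);
          }
        }
      } else if (outcome == 1) {
        // phasic DA window after the reward; proto-weights only decay
        // (place cells are deactivated once the platform is reached)
        int nb = (int) std::lround(t_da_ms / dt_move);
        double dec = std::exp(-dt_move / tau_e_da);
        double g = 1.0 / esc_da;
        for (int b = 0; b < nb; ++b) {
          g *= dec;
          double f = eta_da * rda_amp * g * dt_move;
          for (size_t idx = 0; idx < Gda.size(); ++idx) {
            double d = f * Gda[idx];
            dw_raw[idx] += d;
            w[idx] = clampd(w[idx] + d, w_min, w_max);
          }
        }
      }
    }
  }

  NumericMatrix w_out(n_act, n_pc);
  std::copy(w.begin(), w.end(), w_out.begin());
  for (size_t idx = 0; idx < w.size(); ++idx) {
    if (!std::isfinite(w[idx]))
      stop("non-finite synaptic weight: integration diverged");
  }

  NumericMatrix gda_out(n_act, n_pc), g5_out(n_act, n_pc);
  for (size_t idx = 0; idx < Gda.size(); ++idx) {
    gda_out[idx] = Gda[idx] / esc_da;   // Gamma_DA at episode end
    g5_out[idx]  = G5[idx] / esc_5;     // Gamma_5HT at episode end
  }

  List out = List::create(
    _["outcome"] = outcome,
    _["latency"] = t_out / 1000.0,
    _["w"] = w_out,
    _["dw_raw"] = dw_raw,
    _["gamma_da"] = gda_out,
    _["gamma_5ht"] = g5_out,
    _["final_pos"] = NumericVector::create(px, py));
  if (record_traj) {
    NumericMatrix tr(traj_x.size(), 2);
    for (size_t r = 0; r < traj_x.size(); ++r) { tr(r, 0) = traj_x[r]; tr(r, 1) = traj_y[r]; }
    out["trajectory"] = tr;
  }
  if (record_spikes) {
    out["place_spikes"] = DataFrame::create(_["t"] = sp_t_pre, _["cell"] = sp_i_pre);
    out["action_spikes"] = DataFrame::create(_["t"] = sp_t_post, _["neuron"] = sp_i_post);
  }
  return out;
}
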