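// Conductance-based leaky integrate-and-fire network core.
//
// Euler forward integration of
//   C_m dV/dt = -g_m (V - V_L) - I_syn - I_AHP + I_pre
// with I_syn = g_AMPA (V - V_E) + g_NMDA B(V) (V - V_E) + g_GABA (V - V_I),
// I_AHP = g_ahp * Ca * (V - V_K) (spike-triggered adaptation, hyperpolarizing
// for V > V_K), and I_pre = mult * (bias + sigma * white noise), the noise
// increment scaled by sqrt(dt) so its statistics are dt-invariant.
//
// Short-term plasticity (utilization/resource dynamics) runs event-driven on
// every synapse; pair-based STDP with exponential timing windows runs on
// excitatory-excitatory synapses. Units: mV, ms, nS, pF, pA.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// PRNG: xoshiro256** seeded via splitmix64, plus a Marsaglia-Tsang ziggurat
// for standard normals. The integration loop draws one normal per neuron per
// step, so the sampler has to be table-based.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct Ziggurat {
  // 128-level ziggurat for the standard normal (Marsaglia & Tsang 2000)
  double wn[128], fn[128];
  uint32_t kn[128];
  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
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
  inline double draw(Xoshiro& rng) {
    for (;;) {
      uint64_t u = rng.next();
      int32_t hz = (int32_t)(u & 0xffffffffu);
      int iz = (int)((u >> 32) & 127u);
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      // tail / wedge
      const double r = 3.442619855899;
      double x, y;
      if (iz == 0) {
        do {
          x = -std::log(rng.unif()) / r;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x)) {
        return x;
      }
      // retry with fresh bits
    }
  }
};

// NMDA voltage-dependent magnesium unblock (Jahr & Stevens):
// B(V) = 1 / (1 + [Mg]/3.57 * exp(-0.062 V)), tabulated for speed.
struct BTable {
  std::vector<double> tab;
  double v0, inv_step;
  int n;
  BTable(double mg) : v0(-150.0), inv_step(10.0), n(2001) {
    tab.resize(n);
    for (int i = 0; i < n; ++i) {
      double v = v0 + i / inv_step;
      tab[i] = 1.0 / (1.0 + mg / 3.57 * std::exp(-0.062 * v));
    }
  }
  inline double operator()(double v) const {
    int i = (int)((v - v0) * inv_step + 0.5);
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return tab[i];
  }
};

static inline double getpar(const List& p, const char* name) {
  return as<double>(p[name]);
}

// exp(-x) for x >= 0, tabulated with linear interpolation (event-loop hot
// path: short-term-plasticity recovery factors)
struct NegExpTable {
  std::vector<double> tab;
  double x_max, scale;
  int n;
  NegExpTable() : x_max(30.0), n(4096) {
    scale = (n - 1) / x_max;
    tab.resize(n);
    for (int i = 0; i < n; ++i) tab[i] = std::exp(-i / scale);
  }
  inline double operator()(double x) const {
    if (x >= x_max) return 0.0;
    const double f = x * scale;
    const int i = (int)f;
    const double w = f - i;
    return tab[i] * (1.0 - w) + tab[i + 1] * w;
  }
};

// [[Rcpp::export]]
List sim_core(int n_e, int n_i,
              IntegerVector edge_pre, IntegerVector edge_post,
              IntegerVector out_ptr, IntegerVector out_idx,
              IntegerVector in_ee_ptr, IntegerVector in_ee_idx,
              LogicalVector edge_is_ee,
              List params,
              NumericVector bias, NumericVector sigma,
              NumericVector phase_dur_ms, LogicalVector phase_record,
              NumericMatrix phase_mult,
              double dt, double seed,
              IntegerVector record_v_idx) {
  const int n = n_e + n_i;
  const int n_edges = edge_pre.size();
  const int n_phases = phase_dur_ms.size();

  // --- parameters -----------------------------------------------------------
  const double v_l = getpar(params, "V_L");
  const double v_th = getpar(params, "V_thresh");
  const double v_reset = getpar(params, "V_reset");
  const double v_e_rev = getpar(params, "V_E_rev");
  const double v_i_rev = getpar(params, "V_I_rev");
  const double v_k = getpar(params, "V_K");
  const double c_e = getpar(params, "C_m_e"), c_i = getpar(params, "C_m_i");
  const double gm_e = getpar(params, "g_m_e"), gm_i = getpar(params, "g_m_i");
  const double tref_e = getpar(params, "t_ref_e");
  const double tref_i = getpar(params, "t_ref_i");
  const double tau_ampa = getpar(params, "tau_ampa");
  const double tau_nmda = getpar(params, "tau_nmda");
  const double tau_gaba = getpar(params, "tau_gaba");
  const double g_ampa = getpar(params, "g_ampa") * getpar(params, "ampa_scale");
  const double g_nmda = getpar(params, "g_nmda");
  const double g_gaba = getpar(params, "g_gaba");
  const double alpha_ca = getpar(params, "alpha_ca");
  const double tau_ca = getpar(params, "tau_ca");
  const double g_ahp = getpar(params, "g_ahp");
  const double stp_u = getpar(params, "stp_U");
  const double tau_rec = getpar(params, "stp_tau_rec");
  const double tau_facil = getpar(params, "stp_tau_facil");
  const double a_plus = getpar(params, "stdp_A_plus");
  const double a_minus = getpar(params, "stdp_A_minus");
  const double tau_plus = getpar(params, "stdp_tau_plus");
  const double tau_minus = getpar(params, "stdp_tau_minus");
  const double w_max = getpar(params, "stdp_w_max");
  const double w_init = getpar(params, "stdp_w_init");
  const double mg = getpar(params, "mg_mM");
  const double max_rate = getpar(params, "max_rate_guard");
  const double v_init_sd = getpar(params, "v_init_sd");

  // --- derived constants ----------------------------------------------------
  const double dec_a = std::exp(-dt / tau_ampa);
  const double dec_n = std::exp(-dt / tau_nmda);
  const double dec_g = std::exp(-dt / tau_gaba);
  const double dec_ca = std::exp(-dt / tau_ca);
  const double sqdt = std::sqrt(dt);
  BTable btab(mg);
  Xoshiro rng((uint64_t)seed);
  Ziggurat zig;

  std::vector<double> dt_c(n), gmv(n), noise_c(n), biasv(n);
  std::vector<int> ref_steps(n);
  for (int i = 0; i < n; ++i) {
    const bool exc = i < n_e;
    const double c = exc ? c_e : c_i;
    dt_c[i] = dt / c;
    gmv[i] = exc ? gm_e : gm_i;
    noise_c[i] = sigma[i] * sqdt / c;
    biasv[i] = bias[i];
    ref_steps[i] = (int)std::ceil((exc ? tref_e : tref_i) / dt);
  }

  // --- state ----------------------------------------------------------------
  std::vector<double> V(n), ga(n, 0.0), gn(n, 0.0), gg(n, 0.0), ca(n, 0.0);
  std::vector<int> refr(n, 0);
  for (int i = 0; i < n; ++i) V[i] = v_l + v_init_sd * zig.draw(rng);

  std::vector<double> syn_u(n_edges), syn_x(n_edges, 1.0),
      syn_last(n_edges, -1e12), syn_w(n_edges);
  for (int s = 0; s < n_edges; ++s) {
    syn_u[s] = stp_u;
    syn_w[s] = edge_is_ee[s] ? w_init : 1.0;
  }
  // STDP traces, decayed once per step (cheaper than event-driven decay in
  // high-rate regimes where every spike touches hundreds of synapses)
  std::vector<double> tr_pre(n, 0.0), tr_post(n, 0.0);
  const double dec_plus = std::exp(-dt / tau_plus);
  const double dec_minus = std::exp(-dt / tau_minus);
  NegExpTable nexp;

  std::vector<double> sp_t;
  std::vector<int> sp_i;
  sp_t.reserve(1 << 20);
  sp_i.reserve(1 << 20);

  // voltage log for diagnostics/tests
  const int n_rec_v = record_v_idx.size();
  long total_steps = 0;
  for (int p = 0; p < n_phases; ++p)
    total_steps += (long)std::llround(phase_dur_ms[p] / dt);
  NumericMatrix vlog = (n_rec_v > 0)
      ? NumericMatrix((int)total_steps + 1, n_rec_v) : NumericMatrix(0, 0);
  if (n_rec_v > 0)
    for (int k = 0; k < n_rec_v; ++k) vlog(0, k) = V[record_v_idx[k]];

  // record offset: time spent in unrecorded prefix phases
  double rec_offset = 0.0;
  for (int p = 0; p < n_phases && !phase_record[p]; ++p)
    rec_offset += phase_dur_ms[p];

  std::vector<int> spiked;
  spiked.reserve(n);

  long step = 0;
  long spike_count = 0;
  double guard_next_check = 1000.0;  // every simulated second
  long guard_last_count = 0;

  for (int p = 0; p < n_phases; ++p) {
    const long phase_steps = (long)std::llround(phase_dur_ms[p] / dt);
    const bool rec = phase_record[p];
    std::vector<double> mult(n);
    for (int i = 0; i < n; ++i) mult[i] = phase_mult(i, p);

    for (long k = 0; k < phase_steps; ++k, ++step) {
      const double t = step * dt;        // ms, absolute
      spiked.clear();
      for (int i = 0; i < n; ++i) {
        // decay conductances/adaptation, flushing to zero well above the
        // denormal range (denormal operands stall the FPU)
        const double a_ = ga[i] * dec_a; ga[i] = (a_ > 1e-12) ? a_ : 0.0;
        const double n_ = gn[i] * dec_n; gn[i] = (n_ > 1e-12) ? n_ : 0.0;
        const double g_ = gg[i] * dec_g; gg[i] = (g_ > 1e-12) ? g_ : 0.0;
        const double c_ = ca[i] * dec_ca; ca[i] = (c_ > 1e-12) ? c_ : 0.0;
        const double tp_ = tr_pre[i] * dec_plus; tr_pre[i] = (tp_ > 1e-12) ? tp_ : 0.0;
        const double tm_ = tr_post[i] * dec_minus; tr_post[i] = (tm_ > 1e-12) ? tm_ : 0.0;
        if (refr[i] > 0) { --refr[i]; V[i] = v_reset; continue; }
        double v = V[i];
        const double isyn = ga[i] * (v - v_e_rev)
            + gn[i] * btab(v) * (v - v_e_rev)
            + gg[i] * (v - v_i_rev);
        const double iahp = g_ahp * ca[i] * (v - v_k);
        v += dt_c[i] * (-gmv[i] * (v - v_l) - isyn - iahp
                        + mult[i] * biasv[i])
            + mult[i] * noise_c[i] * zig.draw(rng);
        if (v >= v_th) {
          spiked.push_back(i);
          V[i] = v_reset;
          refr[i] = ref_steps[i];
          ca[i] += alpha_ca;
        } else {
          V[i] = v;
        }
        if (!std::isfinite(V[i]))
          stop("non-finite membrane potential at step %ld, neuron %d",
               step, i + 1);
      }

      // synaptic propagation + plasticity, event-driven at spike times
      const double ts = t + dt;  // spike assigned to the end of the step
      spike_count += (long)spiked.size();
      for (int j : spiked) {
        if (rec) {
          sp_t.push_back((ts - rec_offset) * 1e-3);  // seconds, recorded frame
          sp_i.push_back(j + 1);
        }
        const bool pre_exc = j < n_e;
        for (int e = out_ptr[j]; e < out_ptr[j + 1]; ++e) {
          const int s = out_idx[e];
          const int post = edge_post[s];
          // short-term plasticity: recover, (optionally) facilitate, release
          const double el = ts - syn_last[s];
          double x = 1.0 - (1.0 - syn_x[s]) * nexp(el / tau_rec);
          double u;
          if (tau_facil > 0) {
            u = stp_u + (syn_u[s] - stp_u) * nexp(el / tau_facil);
            u = u + stp_u * (1.0 - u);
          } else {
            u = stp_u;
          }
          const double rel = u * x;
          syn_x[s] = x - rel;
          syn_u[s] = u;
          syn_last[s] = ts;
          if (pre_exc) {
            ga[post] += g_ampa * syn_w[s] * rel;
            gn[post] += g_nmda * syn_w[s] * rel;
          } else {
            gg[post] += g_gaba * rel;
          }
          // depression: presynaptic spike after postsynaptic spikes (E-E)
          if (edge_is_ee[s]) {
            double w = syn_w[s] - a_minus * tr_post[post];
            syn_w[s] = (w < 0.0) ? 0.0 : w;
          }
        }
        // potentiation: postsynaptic spike after presynaptic spikes (E-E)
        if (pre_exc) {
          for (int e = in_ee_ptr[j]; e < in_ee_ptr[j + 1]; ++e) {
            const int s = in_ee_idx[e];
            double w = syn_w[s] + a_plus * tr_pre[edge_pre[s]];
            syn_w[s] = (w > w_max) ? w_max : w;
          }
          tr_pre[j] += 1.0;
          tr_post[j] += 1.0;
        }
      }

      if (n_rec_v > 0)
        for (int kk = 0; kk < n_rec_v; ++kk)
          vlog(step + 1, kk) = V[record_v_idx[kk]];

      if (t >= guard_next_check) {
        const long cnt = spike_count;
        if ((cnt - guard_last_count) > (long)(max_rate * n)) {
          stop("runaway activity: > %g spikes/neuron/s around t = %g s "
               "(step %ld)", max_rate, t * 1e-3, step);
        }
        guard_last_count = cnt;
        guard_next_check += 1000.0;
      }
    }
  }

  NumericVector w_out(n_edges);
  for (int s = 0; s < n_edges; ++s) w_out[s] = syn_w[s];

  return List::create(
      _["spike_time"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["spike_neuron"] = IntegerVector(sp_i.begin(), sp_i.end()),
      _["weights"] = w_out,
      _["v_final"] = NumericVector(V.begin(), V.end()),
      _["v_log"] = vlog);
}

// Greedy duplicate-spike rule: keep a spike only if it is at least
// `refractory` seconds after the previously kept spike.
// [[Rcpp::export]]
LogicalVector dedup_times(NumericVector times, double refractory) {
  const int n = times.size();
  LogicalVector keep(n);
  if (n == 0) return keep;
  keep[0] = true;
  double last = times[0];
  for (int i = 1; i < n; ++i) {
    if (times[i] - last > refractory) {
      keep[i] = true;
      last = times[i];
    } else {
      keep[i] = false;
    }
  }
  return keep;
}
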