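// Fixed-step network integrator for IF/GIF inhibitory networks.
//
// Subthreshold dynamics (voltage v relative to the leak reversal, mV):
//   C dv/dt = -g v - g1 w + g_syn (E_syn - v) + [ge]+ (Ee - v) + [gi]+ (Ei - v)
//   tau1 dw/dt = v - w                                (GIF only; g1 = 0 for IF)
// Background conductances ge, gi are latent Ornstein-Uhlenbeck states advanced
// with the exact transition once per step and rectified at the point of use.
// Synaptic conductance decays exponentially (tau_syn) and jumps by ghat per
// delayed presynaptic spike arrival; deliveries go through a ring buffer of
// per-step arrival accumulators. Threshold/reset/refractoriness are evaluated
// once per step; during refractoriness v is clamped at v_reset while w relaxes
// toward v_reset with its own exact exponential update.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// One independent, reproducible engine per (seed, neuron, process) triple.
static std::mt19937_64 make_engine(uint64_t seed, uint64_t unit, uint64_t stream) {
  uint64_t s = splitmix64(seed ^ splitmix64(unit ^ splitmix64(stream + 0x632BE59BD9B4E019ULL)));
  return std::mt19937_64(s);
}

// Butcher's 7-stage sixth-order Runge-Kutta tableau. For the linear system
// with inputs held constant over the step this reproduces exp(z) through z^6.
static const double RKA[7][7] = {
  {0, 0, 0, 0, 0, 0, 0},
  {1.0 / 3, 0, 0, 0, 0, 0, 0},
  {0, 2.0 / 3, 0, 0, 0, 0, 0},
  {1.0 / 12, 1.0 / 3, -1.0 / 12, 0, 0, 0, 0},
  {-1.0 / 16, 9.0 / 8, -3.0 / 16, -3.0 / 8, 0, 0, 0},
  {0, 9.0 / 8, -3.0 / 8, -3.0 / 4, 1.0 / 2, 0, 0},
  {9.0 / 44, -9.0 / 11, 63.0 / 44, 18.0 / 11, 0, -16.0 / 11, 0}
};
static const double RKB[7] = {11.0 / 120, 0, 27.0 / 40, 27.0 / 40,
                              -4.0 / 15, -4.0 / 15, 11.0 / 120};

struct Deriv {
  double gtot_over_C, drive_over_C, g1_over_C, inv_tau1;
  bool gif;
  inline void operator()(double v, double w, double& dv, double& dw) const {
    dv = drive_over_C - gtot_over_C * v - (gif ? g1_over_C * w : 0.0);
    dw = gif ? (v - w) * inv_tau1 : 0.0;
  }
};

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(bool gif, double C, double g, double g1, double tau1,
                double v_th, double v_reset, double tau_ref,
                double ge0, double sigma_e, double gi0, double sigma_i,
                double tau_e, double tau_i, double Ee, double Ei,
                int N, IntegerMatrix delay_steps,
                double ghat, double tau_syn, double E_syn,
                double dt, double t_discard, double t_measure,
                int trace_stride, IntegerVector record_neurons,
                double seed, bool threshold_on, double init_gsyn) {
  const int n_discard = (int)std::lround(t_discard / dt);
  const int n_measure = (int)std::lround(t_measure / dt);
  const int n_total = n_discard + n_measure;
  const int ref_steps = (int)std::lround(tau_ref / dt);
  const bool coupled = (ghat != 0.0) && N > 1;

  // exact OU transition coefficients
  const double ae = std::exp(-dt / tau_e), ai = std::exp(-dt / tau_i);
  const double se = sigma_e * std::sqrt(1.0 - ae * ae);
  const double si = sigma_i * std::sqrt(1.0 - ai * ai);
  const double syn_decay = std::exp(-dt / tau_syn);
  const double w_decay = gif ? std::exp(-dt / tau1) : 1.0;

  std::vector<double> v(N, 0.0), w(N, 0.0), ge(N, ge0), gi(N, gi0),
      gsyn(N, init_gsyn);
  std::vector<int> ref_left(N, 0);

  std::vector<std::mt19937_64> eng_e, eng_i;
  eng_e.reserve(N); eng_i.reserve(N);
  const uint64_t useed = (uint64_t)std::llround(seed);
  for (int i = 0; i < N; ++i) {
    eng_e.push_back(make_engine(useed, (uint64_t)i, 0));
    eng_i.push_back(make_engine(useed, (uint64_t)i, 1));
  }
  std::normal_distribution<double> norm(0.0, 1.0);

  // ring buffer of arrival accumulators
  int max_delay = 1;
  if (coupled) {
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j)
        if (i != j && delay_steps(i, j) > max_delay) max_delay = delay_steps(i, j);
  }
  const int D = max_delay + 1;
  std::vector<double> arrivals(coupled ? (size_t)D * N : (size_t)N, 0.0);

  std::vector<std::vector<double>> spikes(N);
  IntegerVector pop_counts(n_measure > 0 ? n_measure : 0);

  const int n_trace = (trace_stride > 0) ? n_measure / trace_stride : 0;
  NumericVector tr_t(n_trace), tr_v(n_trace), tr_w(n_trace), tr_sd_v(n_trace),
      tr_isyn(n_trace), tr_iint(n_trace);
  const int n_rec = record_neurons.size();
  NumericMatrix rec_v(n_rec > 0 ? n_trace : 0, n_rec);
  NumericMatrix rec_iint(n_rec > 0 ? n_trace : 0, n_rec);
  NumericMatrix rec_isyn(n_rec > 0 ? n_trace : 0, n_rec);
  LogicalMatrix rec_ref(n_rec > 0 ? n_trace : 0, n_rec);

  Deriv f;
  f.gif = gif;
  f.g1_over_C = g1 / C;
  f.inv_tau1 = gif ? 1.0 / tau1 : 0.0;

  double kv[7], kw[7];

  for (int s = 0; s < n_total; ++s) {
    const int m = s - n_discard;  // measurement step index (>= 0 once measuring)

    // (1) background OU, exact transition of the latent (unrectified) state
    for (int i = 0; i < N; ++i) {
      ge[i] = ge0 + (ge[i] - ge0) * ae + se * norm(eng_e[i]);
      gi[i] = gi0 + (gi[i] - gi0) * ai + si * norm(eng_i[i]);
    }

    // (2) synaptic conductance: decay then add arrivals due this step
    if (coupled) {
      double* row = &arrivals[(size_t)(s % D) * N];
      for (int i = 0; i < N; ++i) {
        gsyn[i] = gsyn[i] * syn_decay + row[i];
        row[i] = 0.0;
      }
    } else {
      for (int i = 0; i < N; ++i) gsyn[i] *= syn_decay;
    }

    // (3) advance (v, w) one RK step, conductances constant over the step
    for (int i = 0; i < N; ++i) {
      if (ref_left[i] > 0) {
        // clamped at v_reset; w relaxes toward v_reset exactly
        if (gif) w[i] = v_reset + (w[i] - v_reset) * w_decay;
        v[i] = v_reset;
        --ref_left[i];
        continue;
      }
      const double ger = ge[i] > 0 ? ge[i] : 0.0;
      const double gir = gi[i] > 0 ? gi[i] : 0.0;
      f.gtot_over_C = (g + gsyn[i] + ger + gir) / C;
      f.drive_over_C = (gsyn[i] * E_syn + ger * Ee + gir * Ei) / C;
      for (int st = 0; st < 7; ++st) {
        double vv = v[i], ww = w[i];
        for (int j = 0; j < st; ++j) {
          vv += dt * RKA[st][j] * kv[j];
          ww += dt * RKA[st][j] * kw[j];
        }
        f(vv, ww, kv[st], kw[st]);
      }
      double dv = 0.0, dw = 0.0;
      for (int st = 0; st < 7; ++st) {
        dv += RKB[st] * kv[st];
        dw += RKB[st] * kw[st];
      }
      v[i] += dt * dv;
      w[i] += dt * dw;
      if (!std::isfinite(v[i]))
        stop("non-finite membrane potential: check parameters and step size");
    }

    // (4) threshold crossing, reset, refractoriness, delayed deliveries
    if (threshold_on) {
      for (int i = 0; i < N; ++i) {
        if (ref_left[i] == 0 && v[i] >= v_th) {
          const double t_spk = (s + 1) * dt;
          v[i] = v_reset;
          ref_left[i] = ref_steps;
          if (m >= 0) {
            spikes[i].push_back(t_spk - t_discard);
            if (m < n_measure) pop_counts[m] += 1;
          }
          if (coupled) {
            for (int j = 0; j < N; ++j) {
              if (j == i) continue;
              const int at = (s + delay_steps(i, j)) % D;
              arrivals[(size_t)at * N + j] += ghat;
            }
          }
        }
      }
    }

    // (5) mean-field and per-neuron trace samples
    if (m >= 0 && trace_stride > 0 && (m + 1) % trace_stride == 0) {
      const int q = (m + 1) / trace_stride - 1;
      if (q < n_trace) {
        double sv = 0, sv2 = 0, sw = 0, ssyn = 0, sint = 0;
        for (int i = 0; i < N; ++i) {
          sv += v[i];
          sv2 += v[i] * v[i];
          sw += w[i];
          ssyn += gsyn[i] * (E_syn - v[i]);
          sint += -g * v[i] - (gif ? g1 * w[i] : 0.0);
        }
        tr_t[q] = (m + 1) * dt;
        tr_v[q] = sv / N;
        tr_w[q] = sw / N;
        const double var = (N > 1) ? (sv2 - sv * sv / N) / (N - 1) : 0.0;
        tr_sd_v[q] = var > 0 ? std::sqrt(var) : 0.0;
        tr_isyn[q] = ssyn / N;
        tr_iint[q] = sint / N;
        for (int r = 0; r < n_rec; ++r) {
          const int i = record_neurons[r];
          rec_v(q, r) = v[i];
          rec_iint(q, r) = -g * v[i] - (gif ? g1 * w[i] : 0.0);
          rec_isyn(q, r) = gsyn[i] * (E_syn - v[i]);
          rec_ref(q, r) = ref_left[i] > 0;
        }
      }
    }
  }

  List spk(N);
  for (int i = 0; i < N; ++i) spk[i] = NumericVector(spikes[i].begin(), spikes[i].end());

  return List::create(
      _["spikes"] = spk, _["pop_counts"] = pop_counts,
      _["trace"] = DataFrame::create(_["t"] = tr_t, _["v"] = tr_v, _["w"] = tr_w,
                                     _["sd_v"] = tr_sd_v, _["i_syn"] = tr_isyn,
                                     _["i_int"] = tr_iint),
      _["rec_v"] = rec_v, _["rec_iint"] = rec_iint, _["rec_isyn"] = rec_isyn,
      _["rec_refractory"] = rec_ref,
      _["final_v"] = NumericVector(v.begin(), v.end()));
}
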