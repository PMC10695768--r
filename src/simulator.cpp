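#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven LIF network with exact exponential propagators.
//
// State per CA1 neuron: membrane potential V (mV) and one aggregated
// synaptic current I_syn (pA). All synapse types share the PSC decay
// tau_syn, so per-target currents superpose into a single exponential state
// per neuron; transmission events add a jump (A for static synapses,
// A * u * x for plastic ones).
//
// Per active zone with short-term plasticity: the Tsodyks-Markram state
// (x, y, z, u), updated lazily at that zone's transmission events using the
// closed-form inter-event solution (identical algebra to the R-level
// stp_event_trace()).
//
// Sub-threshold update over one step of length dt with background current
// Ib held constant and I_syn decaying exponentially:
//   V <- em V + R (1 - em) Ib + P_syn I_syn
//   P_syn = R * ts/(ts - tm) * (es - em),  em = exp(-dt/tm), es = exp(-dt/ts)
// then I_syn <- es I_syn. This reproduces the analytic PSC and membrane
// response exactly at step boundaries.

struct StpState {
  double x = 1.0, y = 0.0, z = 0.0, u = 0.0;
  long last_step = 0;
};

static inline void stp_decay_state(StpState &s, double dt_ms, double ts,
                                   double tr, double tf) {
  if (dt_ms <= 0) return;
  double es = std::exp(-dt_ms / ts);
  double er = std::exp(-dt_ms / tr);
  double cc = 1.0 / ts - 1.0 / tr;
  double B = (std::fabs(cc) < 1e-14) ? s.y * dt_ms / ts : s.y / (ts * cc);
  double z1 = s.z * er + B * (er - es);
  double x1 = s.x + (s.z + B) * (1.0 - er) - (B * ts / tr) * (1.0 - es);
  s.y *= es;
  s.z = z1;
  s.x = x1;
  s.u = (tf > 0) ? s.u * std::exp(-dt_ms / tf) : 0.0;
}

// [[Rcpp::export]]
List lif_network_run(IntegerVector event_step,   // sorted, 0-based step index
                     IntegerVector event_az,     // 0-based active-zone index
                     IntegerVector az_target,    // 0-based CA1 index per AZ
                     IntegerVector az_plastic,   // 0 static, 1 plastic
                     NumericVector az_a,         // weight A per AZ (pA)
                     NumericVector az_u,         // U per AZ (0 for static)
                     NumericVector az_tau_rec,
                     NumericVector az_tau_fac,
                     int n_ca1, long n_steps, double dt_ms,
                     double tau_m, double r_in, double v_th, double v_reset,
                     int ref_steps, double tau_syn,
                     double mu_b, double sigma_b, int noise_steps,
                     int record_neuron) {        // 0-based, -1 = none
  RNGScope scope;
  const int n_az = az_target.size();
  const long n_ev = event_step.size();

  std::vector<double> V(n_ca1, 0.0), Isyn(n_ca1, 0.0), Ib(n_ca1, mu_b);
  std::vector<int> refr(n_ca1, 0);
  std::vector<StpState> stp(n_az);
  std::vector<std::vector<double>> spikes(n_ca1);

  const double em = std::exp(-dt_ms / tau_m);
  const double es = std::exp(-dt_ms / tau_syn);
  const double p_bg = r_in * (1.0 - em);
  const double p_syn = r_in * tau_syn / (tau_syn - tau_m) * (es - em);

  NumericVector v_trace, i_trace;
  bool record = record_neuron >= 0;
  if (record) {
    v_trace = NumericVector(n_steps);
    i_trace = NumericVector(n_steps);
  }

  long ev = 0;
  for (long step = 0; step < n_steps; ++step) {
    if (sigma_b > 0 && step % noise_steps == 0) {
      for (int i = 0; i < n_ca1; ++i)
        Ib[i] = mu_b + sigma_b * norm_rand();
    }
    // transmission events scheduled at the start of this step
    while (ev < n_ev && event_step[ev] == step) {
      int k = event_az[ev];
      if (az_plastic[k]) {
        StpState &s = stp[k];
        stp_decay_state(s, (step - s.last_step) * dt_ms, tau_syn,
                        az_tau_rec[k], az_tau_fac[k]);
        s.last_step = step;
        s.u += az_u[k] * (1.0 - s.u);
        double rel = s.u * s.x;
        s.x -= rel;
        s.y += rel;
        Isyn[az_target[k]] += az_a[k] * rel;
      } else {
        Isyn[az_target[k]] += az_a[k];
      }
      ++ev;
    }
    for (int i = 0; i < n_ca1; ++i) {
      if (refr[i] > 0) {
        --refr[i];
        V[i] = v_reset;
      } else {
        V[i] = em * V[i] + p_bg * Ib[i] + p_syn * Isyn[i];
        if (V[i] >= v_th) {
          spikes[i].push_back((step + 1) * dt_ms / 1000.0);
          V[i] = v_reset;
          refr[i] = ref_steps;
        }
      }
      Isyn[i] *= es;
    }
    if (record) {
      v_trace[step] = V[record_neuron];
      i_trace[step] = Isyn[record_neuron];
    }
  }

  List out_spikes(n_ca1);
  for (int i = 0; i < n_ca1; ++i)
    out_spikes[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  List out = List::create(Named("spikes") = out_spikes);
  if (record) {
    out["v_trace"] = v_trace;
    out["i_trace"] = i_trace;
  }
  return out;
}
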