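// Exponential-Euler integrator for the conductance-based LIF network.
//
// Units: mV, ms, nS, pA, pF (consistent: nS*mV = pA, pF*mV/ms = pA).
// Conductances decay exactly between updates; a presynaptic spike increments
// the target conductance by the pathway peak conductance after the recurrent
// delay (minimum one step). External drive is either an internal compound
// Poisson process per neuron (thalamic + background, drawn from R's RNG so
// runs are reproducible under set.seed) or a caller-supplied event schedule.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List lif_simulate_cpp(double C, double gL, double VL, double Vexc, double Vinh,
                      double Vtheta, double Vreset, double t_ref, double tau_syn,
                      int NE, int NI,
                      IntegerVector out_ptr, IntegerVector out_idx,
                      double w_ee, double w_ei, double w_ie, double w_ii,
                      double delay_ms,
                      double rate_thal_hz, double rate_bkg_hz,
                      double w_thal_e, double w_thal_i, double w_bkg,
                      double i_ext_pA, double g_exc_clamp_nS,
                      double duration_ms, double dt_ms,
                      bool init_uniform, bool apply_threshold,
                      bool record_v, double vmean_discard_ms,
                      Nullable<List> ext_events_) {
  const int N = NE + NI;
  const int n_steps = (int)std::lround(duration_ms / dt_ms);
  const double decay = std::exp(-dt_ms / tau_syn);
  // conductances are taken at the step midpoint for the voltage update
  // (second-order accurate in the synaptic time course)
  const double half_decay = std::exp(-0.5 * dt_ms / tau_syn);
  const int ref_steps = (int)std::lround(t_ref / dt_ms);
  const int d_steps = std::max(0, (int)std::lround(delay_ms / dt_ms));
  const int n_slots = d_steps + 1;

  std::vector<double> V(N), ge(N, 0.0), gi(N, 0.0);
  std::vector<int> refc(N, 0);
  std::vector<double> buf_ge((size_t)n_slots * N, 0.0);
  std::vector<double> buf_gi((size_t)n_slots * N, 0.0);

  // initial conditions (draw order fixed for reproducibility)
  for (int i = 0; i < N; ++i) {
    V[i] = init_uniform ? R::runif(VL, Vtheta) : VL;
  }

  // external drive: internal Poisson or supplied schedule
  const bool use_sched = ext_events_.isNotNull();
  std::vector<double> next_thal(N, R_PosInf), next_bkg(N, R_PosInf);
  const double scale_thal = rate_thal_hz > 0 ? 1000.0 / rate_thal_hz : 0.0;
  const double scale_bkg = rate_bkg_hz > 0 ? 1000.0 / rate_bkg_hz : 0.0;
  List sched;
  std::vector<const double*> ev_t(N, nullptr), ev_w(N, nullptr);
  std::vector<int> ev_n(N, 0), ev_pos(N, 0);
  if (use_sched) {
    sched = ext_events_.get();
    if (sched.size() != N) stop("ext_events must have one element per neuron");
    for (int i = 0; i < N; ++i) {
      NumericMatrix m = sched[i];
      ev_n[i] = m.nrow();
      if (ev_n[i] > 0) { ev_t[i] = &m(0, 0); ev_w[i] = &m(0, 1); }
    }
  } else {
    for (int i = 0; i < N; ++i) {
      if (rate_thal_hz > 0) next_thal[i] = R::rexp(scale_thal);
      if (rate_bkg_hz > 0) next_bkg[i] = R::rexp(scale_bkg);
    }
  }

  std::vector<int> spk_id;
  std::vector<double> spk_t;
  spk_id.reserve(4096);
  spk_t.reserve(4096);

  NumericMatrix Vrec = record_v ? NumericMatrix(n_steps, N) : NumericMatrix(0, 0);
  std::vector<double> vsum(vmean_discard_ms >= 0 ? N : 0, 0.0);
  long vcount = 0;

  for (int step = 0; step < n_steps; ++step) {
    const double t1 = (step + 1) * dt_ms;
    const int slot = step % n_slots;
    const int wslot = (step + d_steps) % n_slots;
    double* cur_ge = &buf_ge[(size_t)slot * N];
    double* cur_gi = &buf_gi[(size_t)slot * N];
    const bool acc_v = (vmean_discard_ms >= 0) && (t1 >= vmean_discard_ms);
    if (acc_v) ++vcount;

    for (int i = 0; i < N; ++i) {
      // conductance decay, then increments arriving at this step boundary
      double g_e = ge[i] * decay + cur_ge[i];
      double g_i = gi[i] * decay + cur_gi[i];
      cur_ge[i] = 0.0;
      cur_gi[i] = 0.0;
      if (use_sched) {
        while (ev_pos[i] < ev_n[i] && ev_t[i][ev_pos[i]] < t1) {
          g_e += ev_w[i][ev_pos[i]];
          ++ev_pos[i];
        }
      } else {
        const double w_th = (i < NE) ? w_thal_e : w_thal_i;
        while (next_thal[i] < t1) { g_e += w_th; next_thal[i] += R::rexp(scale_thal); }
        while (next_bkg[i] < t1) { g_e += w_bkg; next_bkg[i] += R::rexp(scale_bkg); }
      }
      ge[i] = g_e;
      gi[i] = g_i;

      if (refc[i] > 0) {
        --refc[i];
        V[i] = Vreset;
      } else {
        const double g_exc = g_e * half_decay + g_exc_clamp_nS;
        const double g_inh = g_i * half_decay;
        const double gtot = gL + g_exc + g_inh;
        const double Vinf = (gL * VL + g_exc * Vexc + g_inh * Vinh + i_ext_pA) / gtot;
        V[i] = Vinf + (V[i] - Vinf) * std::exp(-gtot * dt_ms / C);
        if (!std::isfinite(V[i])) {
          stop("integration failure: non-finite membrane potential (neuron %d, t = %.3f ms)",
               i + 1, t1);
        }
        if (apply_threshold && V[i] >= Vtheta) {
          spk_id.push_back(i + 1);
          spk_t.push_back(t1);
          V[i] = Vreset;
          refc[i] = ref_steps;
          const bool src_e = i < NE;
          double* tbuf_e = &buf_ge[(size_t)wslot * N];
          double* tbuf_i = &buf_gi[(size_t)wslot * N];
          for (int k = out_ptr[i]; k < out_ptr[i + 1]; ++k) {
            const int tgt = out_idx[k];
            const bool tgt_e = tgt < NE;
            if (src_e) tbuf_e[tgt] += tgt_e ? w_ee : w_ei;
            else       tbuf_i[tgt] += tgt_e ? w_ie : w_ii;
          }
        }
      }
      if (acc_v) vsum[i] += V[i];
      if (record_v) Vrec(step, i) = V[i];
    }
  }

  List out = List::create(
    Named("spike_neuron") = IntegerVector(spk_id.begin(), spk_id.end()),
    Named("spike_time") = NumericVector(spk_t.begin(), spk_t.end()),
    Named("n_steps") = n_steps);
  if (vmean_discard_ms >= 0 && vcount > 0) {
    NumericVector vm(N);
    for (int i = 0; i < N; ++i) vm[i] = vsum[i] / vcount;
    out["vmean"] = vm;
  }
  if (record_v) out["V"] = Vrec;
  return out;
}
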