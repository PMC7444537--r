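// Clock-driven integration of a conductance-based LIF network with
// alpha-function synapses and delayed spike delivery.
//
// Units: mV, ms, nS, pF, pA (nS * mV = pA; pA / pF = mV/ms).
//
// Synaptic state per neuron and transmitter class (exc/inh) is held as two
// linear kernel variables (g, h):
//   dg/dt = (h - g) / tau,   dh/dt = -h / tau
// A presynaptic impulse of peak conductance gbar adds e * gbar to h, so the
// conductance transient is gbar * e * (t/tau) * exp(-t/tau), i.e. an alpha
// function peaking at gbar when t = tau. Summation over synapses and events
// is exact because the kernel is linear.
//
// Membrane: C dV/dt = -G_leak (V - E_leak) - g_e (V - E_exc) - g_i (V - E_inh) + I_ext
// integrated with classical fixed-step 4th-order Runge-Kutta on the coupled
// (V, g_e, h_e, g_i, h_i) system. Threshold crossings are detected at step
// boundaries; V is reset and clamped for the refractory period while the
// conductance states keep evolving.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Poisson draw by Knuth inversion; efficient for the small per-step rates
// (lambda ~ 1) produced by lumping the background drive into one process.
static inline int rpois_knuth(double exp_neg_lambda) {
  int k = 0;
  double p = unif_rand();
  while (p > exp_neg_lambda) {
    ++k;
    p *= unif_rand();
  }
  return k;
}

struct Deriv {
  double dv, dge, dhe, dgi, dhi;
};

// [[Rcpp::export]]
List sim_core(NumericVector v_init,
              double c_m, double g_leak, double e_leak,
              double v_th, double v_reset, double tau_ref,
              double e_exc, double e_inh, double tau_exc, double tau_inh,
              IntegerVector syn_ptr,     // CSR row pointers by presynaptic id, length n+1
              IntegerVector syn_post,    // 0-based postsynaptic ids
              NumericVector syn_g,       // peak conductance (nS)
              IntegerVector syn_inh,     // 1 = inhibitory transmitter, 0 = excitatory
              IntegerVector syn_dstep,   // delay in steps, >= 1
              NumericVector bg_lambda,   // expected background events per step per neuron
              NumericVector bg_g,        // peak conductance of one background event (nS)
              IntegerVector ext_step,    // external excitatory impulses, sorted by step
              IntegerVector ext_target,
              NumericVector ext_g,
              NumericVector i_ext,       // constant injected current per neuron (pA)
              double dt, int n_steps,
              IntegerVector record_idx,  // 0-based neuron ids to record V from
              int record_every) {        // in steps; 0 disables recording
  const int n = v_init.size();
  const double E = std::exp(1.0);

  // ring buffers for delayed conductance impulses
  int max_d = 1;
  for (int s = 0; s < syn_dstep.size(); ++s)
    if (syn_dstep[s] > max_d) max_d = syn_dstep[s];
  const int L = max_d + 2;
  std::vector<double> buf_e((size_t)L * n, 0.0), buf_i((size_t)L * n, 0.0);

  std::vector<double> v(n), ge(n, 0.0), he(n, 0.0), gi(n, 0.0), hi(n, 0.0);
  std::vector<int> refr_until(n, 0);  // first step index at which spiking is allowed again
  for (int i = 0; i < n; ++i) v[i] = v_init[i];

  std::vector<double> exp_neg_lambda(n);
  bool any_bg = false;
  for (int i = 0; i < n; ++i) {
    exp_neg_lambda[i] = std::exp(-bg_lambda[i]);
    if (bg_lambda[i] > 0) any_bg = true;
  }

  const int refr_steps = (int)std::lround(tau_ref / dt);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(4096);
  spike_t.reserve(4096);

  const int n_rec = record_idx.size();
  int n_samples = 0;
  if (record_every > 0 && n_rec > 0 && n_steps > 0)
    n_samples = (n_steps - 1) / record_every + 1;
  NumericMatrix vm(n_samples > 0 ? n_samples : 0, n_rec);
  NumericVector vm_t(n_samples > 0 ? n_samples : 0);

  const double inv_te = 1.0 / tau_exc, inv_ti = 1.0 / tau_inh;
  const double inv_c = 1.0 / c_m;

  int ext_ptr = 0;
  const int n_ext = ext_step.size();
  int sample = 0;

  for (int step = 0; step < n_steps; ++step) {
    // voltage samples at time step * dt (state before integrating this step)
    if (n_samples > 0 && step % record_every == 0) {
      for (int r = 0; r < n_rec; ++r) vm(sample, r) = v[record_idx[r]];
      vm_t[sample] = step * dt;
      ++sample;
    }

    // deliver impulses scheduled for this step
    const size_t slot = (size_t)(step % L) * n;
    for (int i = 0; i < n; ++i) {
      he[i] += buf_e[slot + i];
      hi[i] += buf_i[slot + i];
      buf_e[slot + i] = 0.0;
      buf_i[slot + i] = 0.0;
    }

    // lumped Poisson background (excitatory)
    if (any_bg) {
      for (int i = 0; i < n; ++i) {
        if (bg_lambda[i] <= 0) continue;
        int k = rpois_knuth(exp_neg_lambda[i]);
        if (k > 0) he[i] += E * bg_g[i] * k;
      }
    }

    // external (stimulus) impulses
    while (ext_ptr < n_ext && ext_step[ext_ptr] == step) {
      he[ext_target[ext_ptr]] += E * ext_g[ext_ptr];
      ++ext_ptr;
    }

    // RK4 on (V, ge, he, gi, hi); refractory neurons integrate conductances only
    for (int i = 0; i < n; ++i) {
      const bool clamped = step < refr_until[i];
      const double v0 = v[i], ge0 = ge[i], he0 = he[i], gi0 = gi[i], hi0 = hi[i];
      const double iext = i_ext[i];

      Deriv k1, k2, k3, k4;
      // stage 1
      k1.dge = (he0 - ge0) * inv_te; k1.dhe = -he0 * inv_te;
      k1.dgi = (hi0 - gi0) * inv_ti; k1.dhi = -hi0 * inv_ti;
      k1.dv = (-g_leak * (v0 - e_leak) - ge0 * (v0 - e_exc) - gi0 * (v0 - e_inh) + iext) * inv_c;
      // stage 2
      {
        const double vv = v0 + 0.5 * dt * k1.dv;
        const double g2 = ge0 + 0.5 * dt * k1.dge, h2 = he0 + 0.5 * dt * k1.dhe;
        const double gi2 = gi0 + 0.5 * dt * k1.dgi, hi2 = hi0 + 0.5 * dt * k1.dhi;
        k2.dge = (h2 - g2) * inv_te; k2.dhe = -h2 * inv_te;
        k2.dgi = (hi2 - gi2) * inv_ti; k2.dhi = -hi2 * inv_ti;
        k2.dv = (-g_leak * (vv - e_leak) - g2 * (vv - e_exc) - gi2 * (vv - e_inh) + iext) * inv_c;
      }
      // stage 3
      {
        const double vv = v0 + 0.5 * dt * k2.dv;
        const double g3 = ge0 + 0.5 * dt * k2.dge, h3 = he0 + 0.5 * dt * k2.dhe;
        const double gi3 = gi0 + 0.5 * dt * k2.dgi, hi3 = hi0 + 0.5 * dt * k2.dhi;
        k3.dge = (h3 - g3) * inv_te; k3.dhe = -h3 * inv_te;
        k3.dgi = (hi3 - gi3) * inv_ti; k3.dhi = -hi3 * inv_ti;
        k3.dv = (-g_leak * (vv - e_leak) - g3 * (vv - e_exc) - gi3 * (vv - e_inh) + iext) * inv_c;
      }
      // stage 4
      {
        const double vv = v0 + dt * k3.dv;
        const double g4 = ge0 + dt * k3.dge, h4 = he0 + dt * k3.dhe;
        const double gi4 = gi0 + dt * k3.dgi, hi4 = hi0 + dt * k3.dhi;
        k4.dge = (h4 - g4) * inv_te; k4.dhe = -h4 * inv_te;
        k4.dgi = (hi4 - gi4) * inv_ti; k4.dhi = -hi4 * inv_ti;
        k4.dv = (-g_leak * (vv - e_leak) - g4 * (vv - e_exc) - gi4 * (vv - e_inh) + iext) * inv_c;
      }
      const double w = dt / 6.0;
      ge[i] = ge0 + w * (k1.dge + 2 * k2.dge + 2 * k3.dge + k4.dge);
      he[i] = he0 + w * (k1.dhe + 2 * k2.dhe + 2 * k3.dhe + k4.dhe);
      gi[i] = gi0 + w * (k1.dgi + 2 * k2.dgi + 2 * k3.dgi + k4.dgi);
      hi[i] = hi0 + w * (k1.dhi + 2 * k2.dhi + 2 * k3.dhi + k4.dhi);
      if (clamped) {
        v[i] = v_reset;
      } else {
        v[i] = v0 + w * (k1.dv + 2 * k2.dv + 2 * k3.dv + k4.dv);
      }
    }

    // threshold detection at the step boundary, spike time (step + 1) * dt
    for (int i = 0; i < n; ++i) {
      if (step < refr_until[i] || v[i] < v_th) continue;
      if (!std::isfinite(v[i]))
        stop("membrane potential diverged at step %d (neuron %d)", step, i + 1);
      spike_id.push_back(i);
      spike_t.push_back((step + 1) * dt);
      v[i] = v_reset;
      refr_until[i] = step + 1 + refr_steps;
      for (int s = syn_ptr[i]; s < syn_ptr[i + 1]; ++s) {
        const size_t tslot = (size_t)((step + 1 + syn_dstep[s]) % L) * n + syn_post[s];
        if (syn_inh[s]) buf_i[tslot] += E * syn_g[s];
        else            buf_e[tslot] += E * syn_g[s];
      }
    }
  }

  return List::create(_["spike_id"] = wrap(spike_id),
                      _["spike_time"] = wrap(spike_t),
                      _["vm"] = vm,
                      _["vm_time"] = vm_t,
                      _["v_final"] = wrap(v));
}
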