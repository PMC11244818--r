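#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Full network integration: EIF membrane equation (forward Euler), exponential
// synaptic filters (exact per-step decay), and the local voltage-based
// plasticity rule on E->E synapses. Spikes detected at step end are delivered
// to postsynaptic filters at the start of the next step (one-step delay).
//
// Per-step order of operations (documented contract):
//   1. stimulus bookkeeping (event onsets/offsets)
//   2. filter decay (h_E, h_I, s_tilde)
//   3. delivery of last step's spikes: plasticity update (if on) at arrival,
//      PSP jump w/tau_syn using the weight as it was on arrival
//   4. exponential term (V clipped at V_peak), membrane Euler step
//   5. plasticity filter updates (v_tilde, theta) from pre-reset values
//   6. spike detection/reset; s_tilde jump 1/tau_s for E spikes
//
// Edges must be sorted by presynaptic index; edge arrays are 0-based.

// [[Rcpp::export]]
List simulate_network_cpp(IntegerVector edge_pre, IntegerVector edge_post,
                          NumericVector edge_w, IntegerVector edge_class,
                          int n, int n_e, List neuron, List plast,
                          bool plasticity_on, NumericVector V0,
                          NumericVector h_ext, double t0, double duration,
                          double dt, NumericVector ev_onset,
                          NumericVector ev_offset, NumericVector ev_amp,
                          IntegerVector ev_ptr, IntegerVector ev_targets,
                          double class_interval, NumericVector snapshot_times,
                          List init_plast, bool record_spikes = true) {
  const double V_L = neuron["V_L"], V_T = neuron["V_T"],
               Delta_T = neuron["Delta_T"], V_peak = neuron["V_peak"],
               V_r = neuron["V_r"], tau_m_E = neuron["tau_m_E"],
               tau_m_I = neuron["tau_m_I"], tau_syn_E = neuron["tau_syn_E"],
               tau_syn_I = neuron["tau_syn_I"];
  const double A_LTP = plast["A_LTP"], A_LTD = plast["A_LTD"],
               beta = plast["beta"], tau_v = plast["tau_v"],
               tau_s = plast["tau_s"], tau_theta = plast["tau_theta"],
               theta_a = plast["theta_a"], gain = plast["g"],
               gamma = plast["gamma"];

  const int n_edges = edge_w.size();
  if (edge_pre.size() != n_edges || edge_post.size() != n_edges)
    stop("edge arrays have inconsistent lengths");

  // CSR offsets by presynaptic neuron (edges sorted by pre)
  std::vector<int> off(n + 1, 0);
  for (int e = 0; e < n_edges; ++e) {
    if (e > 0 && edge_pre[e] < edge_pre[e - 1])
      stop("edges must be sorted by presynaptic index");
    off[edge_pre[e] + 1]++;
  }
  for (int i = 0; i < n; ++i) off[i + 1] += off[i];

  std::vector<double> w(edge_w.begin(), edge_w.end());
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> hE(n, 0.0), hI(n, 0.0);
  // (plasticity state, synaptic filters and the spike buffer may be
  // seeded below so a resumed session continues bit-exactly)
  std::vector<double> vt(n_e, 0.0), st(n_e, 0.0), th(n_e, 0.0);
  std::vector<int> prev_spk, cur_spk;
  prev_spk.reserve(256);
  cur_spk.reserve(256);
  if (init_plast.size() > 0) {
    NumericVector v0 = init_plast["v_tilde"], s0 = init_plast["s_tilde"],
                  q0 = init_plast["theta"], he0 = init_plast["h_E"],
                  hi0 = init_plast["h_I"];
    IntegerVector pend = init_plast["pending"];
    std::copy(v0.begin(), v0.end(), vt.begin());
    std::copy(s0.begin(), s0.end(), st.begin());
    std::copy(q0.begin(), q0.end(), th.begin());
    std::copy(he0.begin(), he0.end(), hE.begin());
    std::copy(hi0.begin(), hi0.end(), hI.begin());
    prev_spk.assign(pend.begin(), pend.end());
  }
  if ((int)V.size() != n) stop("V0 length must equal n");

  const double decE = std::exp(-dt / tau_syn_E),
               decI = std::exp(-dt / tau_syn_I),
               decS = std::exp(-dt / tau_s);

  const long n_steps = (long)std::llround(duration / dt);

  // stimulus events: starts in given (onset-sorted) order, ends sorted
  const int n_ev = ev_onset.size();
  std::vector<int> end_order(n_ev);
  for (int i = 0; i < n_ev; ++i) end_order[i] = i;
  std::sort(end_order.begin(), end_order.end(),
            [&](int a, int b) { return ev_offset[a] < ev_offset[b]; });
  std::vector<double> h_st(n, 0.0);
  int si = 0, ei = 0;

  // recorders
  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<double> cls_t, cls_w0, cls_w1;
  long n0 = 0, n1 = 0;
  for (int e = 0; e < n_edges; ++e) {
    if (edge_class[e] == 0) n0++;
    else if (edge_class[e] == 1) n1++;
  }
  auto record_class = [&](double tnow) {
    if (class_interval <= 0) return;
    double s0 = 0, s1 = 0;
    for (int e = 0; e < n_edges; ++e) {
      if (edge_class[e] == 0) s0 += w[e];
      else if (edge_class[e] == 1) s1 += w[e];
    }
    cls_t.push_back(tnow);
    cls_w0.push_back(n0 > 0 ? s0 / n0 : NA_REAL);
    cls_w1.push_back(n1 > 0 ? s1 / n1 : NA_REAL);
  };
  record_class(t0);
  double next_class = t0 + class_interval;

  const int n_snap = snapshot_times.size();
  List snaps(n_snap);
  NumericVector snap_done(n_snap);
  int snap_i = 0;

  for (long step = 0; step < n_steps; ++step) {
    const double t = t0 + step * dt;

    // 1. stimulus events active on [onset, offset)
    while (si < n_ev && ev_onset[si] <= t + 1e-9) {
      for (int k = ev_ptr[si]; k < ev_ptr[si + 1]; ++k)
        h_st[ev_targets[k]] += ev_amp[si];
      si++;
    }
    while (ei < n_ev && ev_offset[end_order[ei]] <= t + 1e-9) {
      int ev = end_order[ei];
      for (int k = ev_ptr[ev]; k < ev_ptr[ev + 1]; ++k)
        h_st[ev_targets[k]] -= ev_amp[ev];
      ei++;
    }

    // 2. filter decay
    for (int i = 0; i < n; ++i) { hE[i] *= decE; hI[i] *= decI; }
    for (int i = 0; i < n_e; ++i) st[i] *= decS;

    // 3. deliver previous step's spikes (+ plasticity at arrival)
    for (int j : prev_spk) {
      const bool pre_E = j < n_e;
      for (int e = off[j]; e < off[j + 1]; ++e) {
        const int i = edge_post[e];
        const double w_arr = w[e];
        if (pre_E) {
          hE[i] += w_arr / tau_syn_E;
          if (plasticity_on && i < n_e) {
            const double d = vt[i] - th[i];
            double dw = (d > 0)
              ? A_LTP * std::exp(-beta * w_arr * w_arr) * d
              : A_LTD * d;  // d <= 0: depression A_LTD*(vt-th)
            double wn = w_arr + dw;
            w[e] = wn > 0 ? wn : 0.0;
          }
        } else {
          hI[i] += w_arr / tau_syn_I;
        }
      }
    }
    prev_spk.clear();

    // 4.-6. membrane step, plasticity filters, spike detection
    for (int i = 0; i < n; ++i) {
      const double tau_m = (i < n_e) ? tau_m_E : tau_m_I;
      const double Vc = V[i] < V_peak ? V[i] : V_peak;
      const double expo = Delta_T * std::exp((Vc - V_T) / Delta_T);
      double Vn = V[i] + dt * ((-(V[i] - V_L) + expo) / tau_m +
                               hE[i] + hI[i] + h_st[i] + h_ext[i]);
      if (!std::isfinite(Vn))
        stop("non-finite membrane potential for neuron %d at t = %f ms "
             "(dt = %f ms)", i, t + dt, dt);
      if (i < n_e) {
        vt[i] += dt / tau_v * (-vt[i] + expo);
        th[i] += dt / tau_theta * theta_a *
                 std::tanh(gain * (-th[i] + vt[i] + gamma * st[i]));
      }
      if (Vn >= V_peak) {
        Vn = V_r;
        cur_spk.push_back(i);
        if (record_spikes) {
          spike_t.push_back(t + dt);
          spike_id.push_back(i);
        }
        if (i < n_e) st[i] += 1.0 / tau_s;
      }
      V[i] = Vn;
    }
    std::swap(prev_spk, cur_spk);

    // recorders
    const double t_end = t + dt;
    if (class_interval > 0 && t_end >= next_class - 1e-9) {
      record_class(t_end);
      next_class += class_interval;
    }
    while (snap_i < n_snap && t_end >= snapshot_times[snap_i] - 1e-9) {
      snaps[snap_i] = NumericVector(w.begin(), w.end());
      snap_done[snap_i] = t_end;
      snap_i++;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["w"] = NumericVector(w.begin(), w.end()),
    _["V"] = NumericVector(V.begin(), V.end()),
    _["h_E"] = NumericVector(hE.begin(), hE.end()),
    _["h_I"] = NumericVector(hI.begin(), hI.end()),
    _["v_tilde"] = NumericVector(vt.begin(), vt.end()),
    _["s_tilde"] = NumericVector(st.begin(), st.end()),
    _["theta"] = NumericVector(th.begin(), th.end()),
    _["pending"] = IntegerVector(prev_spk.begin(), prev_spk.end()),
    _["class_t"] = NumericVector(cls_t.begin(), cls_t.end()),
    _["class_w0"] = NumericVector(cls_w0.begin(), cls_w0.end()),
    _["class_w1"] = NumericVector(cls_w1.begin(), cls_w1.end()),
    _["n0"] = (double)n0, _["n1"] = (double)n1,
    _["snapshots"] = snaps, _["snapshot_t"] = snap_done,
    _["t_end"] = t0 + n_steps * dt);
}
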