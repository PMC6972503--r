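#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout shared with R wrappers (see par_vec() in R/presets.R):
// [0] C_m  [1] v_r  [2] v_t  [3] v_peak  [4] a  [5] b  [6] c  [7] d
// [8] k_low  [9] k_high

// One forward-Euler step of the two-variable interneuron model.  The
// voltage-dependent scaling factor k is chosen from the pre-step voltage
// (k_low at or below threshold, k_high above).  Reset is applied after the
// update; the caller timestamps the spike at the end of the step.
static inline bool euler_step(double &V, double &u, const double *p,
                              double I_total, double dt) {
  const double k = (V <= p[2]) ? p[8] : p[9];
  const double dV = (k * (V - p[1]) * (V - p[2]) - u + I_total) * dt / p[0];
  const double du = p[4] * (p[5] * (V - p[1]) - u) * dt;
  V += dV;
  u += du;
  if (V >= p[3]) {
    V = p[6];
    u += p[7];
    return true;
  }
  return false;
}

// [[Rcpp::export]]
NumericVector sim_neuron_cpp(NumericVector par, double I_app, double T,
                             double dt, double V0, double u0) {
  const double *p = REAL(par);
  const int nsteps = (int)std::llround(T / dt);
  double V = V0, u = u0;
  std::vector<double> spikes;
  for (int step = 0; step < nsteps; ++step) {
    if (euler_step(V, u, p, I_app, dt))
      spikes.push_back((step + 1) * dt);
    if (!(std::fabs(V) <= 1e3))  // also catches NaN
      stop("membrane potential diverged at t = %f ms", (step + 1) * dt);
  }
  return wrap(spikes);
}

// Full network integration.  Synaptic gates follow the two closed forms of
// the first-order kinetic synapse: a saturating rise for T_dur = 1 ms after
// each presynaptic spike, exponential decay afterwards.  Because decay is a
// per-step multiplication by a shared constant, the per-postsynaptic-cell
// gate sums R_i = sum_{j in pre(i)} s_j are maintained incrementally: every
// step R is scaled by the decay factor and only sources inside their
// transmitter pulse contribute a correction along their outgoing edges.
// R is rebuilt exactly from s at fixed intervals to stop round-off drift.
//
// out_ptr/out_idx: CSR adjacency by presynaptic source, 0-based.
// [[Rcpp::export]]
List sim_network_cpp(NumericVector par, IntegerVector out_ptr,
                     IntegerVector out_idx, NumericVector I_app,
                     NumericVector V0, double g_syn, double E_syn,
                     double alpha, double beta, double T_dur, double dt,
                     double T_total, double enable_t, double pert_amp,
                     double pert_onset, double pert_width,
                     IntegerVector record_idx, double record_every) {
  const double *p = REAL(par);
  const int N = V0.size();
  const int nsteps = (int)std::llround(T_total / dt);
  const double s_inf = alpha / (alpha + beta);
  const double tau_s = 1.0 / (alpha + beta);
  const double fdec = std::exp(-beta * dt);
  const int refresh_every = 2000;

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> u(N, 0.0);
  std::vector<double> s(N, 0.0), R(N, 0.0);
  std::vector<double> t0(N, 0.0), s0(N, 0.0);
  std::vector<char> in_pulse(N, 0);
  std::vector<int> active;
  std::vector<int> spiked_now;

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(1 << 16);
  sp_t.reserve(1 << 16);

  const int nrec = record_idx.size();
  const int rec_stride = nrec > 0 ? (int)std::llround(record_every / dt) : 0;
  const int nsamp = nrec > 0 ? nsteps / rec_stride + 1 : 0;
  NumericMatrix vtrace(nsamp, nrec);
  NumericVector vtimes(nsamp);
  int samp = 0;

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    const double tnew = t + dt;

    if (nrec > 0 && step % rec_stride == 0) {
      for (int r = 0; r < nrec; ++r) vtrace(samp, r) = V[record_idx[r]];
      vtimes[samp] = t;
      ++samp;
    }

    const double Ipert =
        (t >= pert_onset && t < pert_onset + pert_width) ? pert_amp : 0.0;

    // Euler update with the previous step's gate sums; resets recorded at
    // the end-of-step time.
    spiked_now.clear();
    const double *iapp = REAL(I_app);
    for (int i = 0; i < N; ++i) {
      const double Isyn = g_syn * R[i] * (V[i] - E_syn);
      const double I_total = iapp[i] + Ipert - Isyn;
      if (euler_step(V[i], u[i], p, I_total, dt)) {
        sp_id.push_back(i + 1);
        sp_t.push_back(tnew);
        if (tnew >= enable_t) spiked_now.push_back(i);
      }
      if (!(std::fabs(V[i]) <= 1e3))  // also catches NaN
        stop("membrane potential of neuron %d diverged at t = %f ms", i + 1,
             tnew);
    }

    // Advance all gates to tnew: default exponential decay, then closed-form
    // corrections for sources inside their transmitter pulse.
    for (int i = 0; i < N; ++i) s[i] *= fdec;
    for (int i = 0; i < N; ++i) R[i] *= fdec;
    for (size_t a_i = 0; a_i < active.size();) {
      const int j = active[a_i];
      const double elapsed = tnew - t0[j];
      double snew;
      bool done = false;
      if (elapsed <= T_dur + 1e-12) {
        snew = s_inf + (s0[j] - s_inf) * std::exp(-elapsed / tau_s);
      } else {
        const double st1 = s_inf + (s0[j] - s_inf) * std::exp(-T_dur / tau_s);
        snew = st1 * std::exp(-beta * (elapsed - T_dur));
        done = true;
      }
      const double corr = snew - s[j];
      s[j] = snew;
      if (corr != 0.0)
        for (int e = out_ptr[j]; e < out_ptr[j + 1]; ++e) R[out_idx[e]] += corr;
      if (done) {
        in_pulse[j] = 0;
        active[a_i] = active.back();
        active.pop_back();
      } else {
        ++a_i;
      }
    }

    // New presynaptic spikes restart the pulse clock with the current gate
    // value as s(t0), preserving continuity.
    for (int k = 0; k < (int)spiked_now.size(); ++k) {
      const int j = spiked_now[k];
      t0[j] = tnew;
      s0[j] = s[j];
      if (!in_pulse[j]) {
        in_pulse[j] = 1;
        active.push_back(j);
      }
    }

    if ((step + 1) % refresh_every == 0) {
      std::fill(R.begin(), R.end(), 0.0);
      for (int j = 0; j < N; ++j)
        if (s[j] > 0.0)
          for (int e = out_ptr[j]; e < out_ptr[j + 1]; ++e)
            R[out_idx[e]] += s[j];
    }
  }

  List out = List::create(_["neuron"] = wrap(sp_id), _["time"] = wrap(sp_t));
  if (nrec > 0) {
    out["v_times"] = vtimes[Range(0, samp - 1)];
    out["v_traces"] = vtrace(Range(0, samp - 1), Range(0, nrec - 1));
  }
  return out;
}
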