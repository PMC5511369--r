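#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Leaky single-compartment network integrator with stamped action-potential
// waveforms, ohmic gap junctions and conductance-based chemical synapses.
//
// Units: mV, ms, pA, nS, pF.  C dV/dt = -gL (V - Erest) + I_inj + I_gap + I_syn.
//
// An action potential is not integrated: when V crosses the (adapting)
// threshold the cell's voltage follows a parametric template (quarter-sine
// upstroke to the peak, quarter-cosine downstroke to threshold, half-cosine
// afterhyperpolarization dip), after which integration resumes from the AHP
// minimum.  This keeps spike-shape features (half-width, AHP amplitude, AHP
// time from peak) exactly controllable from the cell parameters.

struct Syn {
  int pre, post;
  double gmax, latency, rise, decay, erev;
  double fr, fd;      // per-substep decay factors
  double norm;        // peak normalisation of (exp(-t/decay) - exp(-t/rise))
  double x, y;        // rise / decay state
  std::vector<double> events; // pending activation times (sorted)
  size_t next_event;
};

static std::vector<double> ap_template(double thr, double peak, double rise_ms,
                                       double halfwidth_ms, double ahp_mV,
                                       double ahp_time_ms, double dt) {
  // fall duration chosen so that width at half peak-to-threshold amplitude
  // equals halfwidth: width = 2/3 (rise + fall) for sine-up / cosine-down.
  double fall = 1.5 * halfwidth_ms - rise_ms;
  double dip = ahp_time_ms - fall; // min reached ahp_time after the peak
  int n_up = (int)std::ceil(rise_ms / dt);
  int n_fall = (int)std::ceil(fall / dt);
  int n_dip = (int)std::ceil(dip / dt);
  std::vector<double> tmpl;
  tmpl.reserve(n_up + n_fall + n_dip + 1);
  for (int k = 1; k <= n_up; ++k) {
    double t = std::min(k * dt, rise_ms);
    tmpl.push_back(thr + (peak - thr) * std::sin(M_PI * t / (2.0 * rise_ms)));
  }
  for (int k = 1; k <= n_fall; ++k) {
    double t = std::min(k * dt, fall);
    tmpl.push_back(thr + (peak - thr) * std::cos(M_PI * t / (2.0 * fall)));
  }
  for (int k = 1; k <= n_dip; ++k) {
    double t = std::min(k * dt, dip);
    tmpl.push_back(thr - ahp_mV * 0.5 * (1.0 - std::cos(M_PI * t / dip)));
  }
  return tmpl;
}

// params: matrix n_cells x 10, columns
//   0 rest_mV, 1 gL_nS, 2 C_pF, 3 thr_mV, 4 peak_mV, 5 rise_ms,
//   6 halfwidth_ms, 7 ahp_mV, 8 ahp_time_ms, 9 adapt_mV (per-spike increment)
// gaps: m x 3 (i, j, g_nS), 1-based cell indices
// syns: s x 7 (pre, post, gmax_nS, latency_ms, rise_ms, decay_ms, erev_mV)
// pulses: p x 4 (cell, onset_ms, duration_ms, amplitude_pA)
// clamp_mode: 0 = current clamp, 1 = voltage clamp; holding_mV used when 1.
// Recorded signal: voltage (mV) for CC cells, clamp current (pA) for VC cells.
// [[Rcpp::export]]
List sim_trial_cpp(NumericMatrix params, NumericMatrix gaps, NumericMatrix syns,
                   NumericMatrix pulses, IntegerVector clamp_mode,
                   NumericVector holding_mV, double trial_length_ms,
                   double dt_ms, int record_every, double process_noise_sd_pA,
                   double common_noise_sd_pA, double common_noise_tau_ms,
                   double adapt_tau_ms) {
  const int n = params.nrow();
  const int n_sub = (int)std::lround(trial_length_ms / dt_ms);
  const int n_samp = n_sub / record_every;
  NumericMatrix traces(n_samp, n);

  std::vector<double> V(n), a(n, 0.0);
  std::vector<int> stamp_pos(n, -1);
  std::vector<std::vector<double> > tmpl(n);
  std::vector<std::vector<double> > spikes(n);
  for (int i = 0; i < n; ++i) {
    V[i] = clamp_mode[i] == 1 ? holding_mV[i] : params(i, 0);
    tmpl[i] = ap_template(params(i, 3), params(i, 4), params(i, 5),
                          params(i, 6), params(i, 7), params(i, 8), dt_ms);
  }

  std::vector<Syn> sy(syns.nrow());
  for (int s = 0; s < syns.nrow(); ++s) {
    Syn& q = sy[s];
    q.pre = (int)syns(s, 0) - 1; q.post = (int)syns(s, 1) - 1;
    q.gmax = syns(s, 2); q.latency = syns(s, 3);
    q.rise = syns(s, 4); q.decay = syns(s, 5); q.erev = syns(s, 6);
    q.fr = std::exp(-dt_ms / q.rise); q.fd = std::exp(-dt_ms / q.decay);
    double tp = (q.decay * q.rise / (q.decay - q.rise)) *
                std::log(q.decay / q.rise);
    q.norm = 1.0 / (std::exp(-tp / q.decay) - std::exp(-tp / q.rise));
    q.x = 0.0; q.y = 0.0; q.next_event = 0;
  }

  const double adapt_decay = std::exp(-dt_ms / adapt_tau_ms);
  const double noise_scale = process_noise_sd_pA / std::sqrt(dt_ms);
  // shared drive modelled as an Ornstein-Uhlenbeck current with stationary
  // s.d. common_noise_sd_pA and correlation time common_noise_tau_ms, so the
  // common modulation is slow relative to the 1 ms correlogram bins
  const double ou_decay = std::exp(-dt_ms / common_noise_tau_ms);
  const double ou_scale = common_noise_sd_pA *
      std::sqrt(1.0 - ou_decay * ou_decay);
  double I_ou = 0.0;

  // hoist parameter and wiring tables out of the hot loop
  std::vector<double> rest(n), gL(n), Cm(n), thr(n), rise(n), adapt(n);
  std::vector<int> mode(n);
  for (int i = 0; i < n; ++i) {
    rest[i] = params(i, 0); gL[i] = params(i, 1); Cm[i] = params(i, 2);
    thr[i] = params(i, 3); rise[i] = params(i, 5); adapt[i] = params(i, 9);
    mode[i] = clamp_mode[i];
  }
  const int n_gap = gaps.nrow();
  std::vector<int> gi(n_gap), gj(n_gap); std::vector<double> gg(n_gap);
  for (int g = 0; g < n_gap; ++g) {
    gi[g] = (int)gaps(g, 0) - 1; gj[g] = (int)gaps(g, 1) - 1;
    gg[g] = gaps(g, 2);
  }
  const int n_pul = pulses.nrow();
  std::vector<int> pc(n_pul); std::vector<double> p_on(n_pul), p_off(n_pul), p_amp(n_pul);
  for (int p = 0; p < n_pul; ++p) {
    pc[p] = (int)pulses(p, 0) - 1; p_on[p] = pulses(p, 1);
    p_off[p] = pulses(p, 1) + pulses(p, 2); p_amp[p] = pulses(p, 3);
  }
  std::vector<double> Inet(n);
  double* tr_ptr = REAL(traces);

  for (int step = 0; step < n_sub; ++step) {
    double t = step * dt_ms;

    // synaptic state update and pending event activation
    for (size_t s = 0; s < sy.size(); ++s) {
      Syn& q = sy[s];
      q.x *= q.fr; q.y *= q.fd;
      while (q.next_event < q.events.size() && q.events[q.next_event] <= t) {
        q.x += 1.0; q.y += 1.0; ++q.next_event;
      }
    }

    if (common_noise_sd_pA > 0)
      I_ou = I_ou * ou_decay + ou_scale * R::norm_rand();
    std::fill(Inet.begin(), Inet.end(), I_ou);
    for (int g = 0; g < n_gap; ++g) {
      double Ig = gg[g] * (V[gj[g]] - V[gi[g]]);
      Inet[gi[g]] += Ig; Inet[gj[g]] -= Ig;
    }
    for (size_t s = 0; s < sy.size(); ++s) {
      Syn& q = sy[s];
      double gsyn = q.gmax * q.norm * (q.y - q.x);
      if (gsyn > 0) Inet[q.post] += gsyn * (q.erev - V[q.post]);
    }
    for (int p = 0; p < n_pul; ++p)
      if (mode[pc[p]] == 0 && t >= p_on[p] && t < p_off[p])
        Inet[pc[p]] += p_amp[p];

    // phase 1: advance every current-clamped cell
    for (int i = 0; i < n; ++i) {
      if (mode[i] == 1) continue;
      a[i] *= adapt_decay;
      if (stamp_pos[i] >= 0) {
        V[i] = tmpl[i][stamp_pos[i]];
        if (++stamp_pos[i] >= (int)tmpl[i].size()) stamp_pos[i] = -1;
      } else {
        double Ileak = -gL[i] * (V[i] - rest[i]);
        double In = 0.0;
        if (process_noise_sd_pA > 0) In = noise_scale * R::norm_rand();
        V[i] += dt_ms / Cm[i] * (Ileak + Inet[i] + In);
        if (!std::isfinite(V[i]))
          stop("integration diverged (non-finite voltage) at t = %f ms", t);
        if (V[i] >= thr[i] + a[i]) {
          double t_peak = t + rise[i];
          spikes[i].push_back(t_peak);
          a[i] += adapt[i];
          V[i] = tmpl[i][0];
          stamp_pos[i] = ((int)tmpl[i].size() > 1) ? 1 : -1;
          for (size_t s = 0; s < sy.size(); ++s)
            if (sy[s].pre == i) sy[s].events.push_back(t_peak + sy[s].latency);
        }
      }
    }

    // phase 2: record; the voltage-clamp readout is recomputed from the
    // freshly updated voltages so stored currents and stored voltages
    // refer to the same instant
    if (step % record_every == 0) {
      R_xlen_t row = step / record_every;
      for (int i = 0; i < n; ++i)
        if (mode[i] == 0)
          tr_ptr[row + (R_xlen_t)n_samp * i] = V[i];
      for (int i = 0; i < n; ++i) {
        if (mode[i] != 1) continue;
        double Ii = 0.0;
        for (int g = 0; g < n_gap; ++g) {
          if (gi[g] == i) Ii += gg[g] * (V[gj[g]] - V[i]);
          else if (gj[g] == i) Ii += gg[g] * (V[gi[g]] - V[i]);
        }
        for (size_t s = 0; s < sy.size(); ++s) {
          if (sy[s].post != i) continue;
          double gsyn = sy[s].gmax * sy[s].norm * (sy[s].y - sy[s].x);
          if (gsyn > 0) Ii += gsyn * (sy[s].erev - V[i]);
        }
        tr_ptr[row + (R_xlen_t)n_samp * i] =
            gL[i] * (V[i] - rest[i]) - Ii;
      }
    }
  }

  List sp(n);
  for (int i = 0; i < n; ++i) sp[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  return List::create(_["traces"] = traces, _["spikes"] = sp);
}
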