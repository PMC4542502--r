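#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step Euler integration of phase oscillators
//   dPhi_n/dt = 2*pi*f_n + K(t) * sum_m W_nm(t) * sin(Phi_m - Phi_n)
// with W(t) a sinusoidal cross-fade between a day and a night coupling graph
// tied to wall-clock time of day, and K(t) raised globally during seizures.
// Only samples falling inside the kept (non-gap) segments are written out,
// so multi-day recordings with a low duty cycle stay small in memory.
//
// edges: E x 4 matrix (i, j, w_day, w_night) with 0-based i < j.
// seg_start/seg_len: kept segments in units of sample steps.
// t0_tod: wall-clock seconds since midnight at t = 0 (for the cross-fade).
// Returns list(x = kept samples (rows) x channels, phase_end = final phases).

// [[Rcpp::export]]
List kuramoto_integrate(NumericVector phase0, NumericVector freq_hz,
                        NumericMatrix edges,
                        double k_high, double k_low,
                        double dt, double n_steps_d,
                        IntegerVector seg_start, IntegerVector seg_len,
                        NumericVector sz_start, NumericVector sz_end,
                        double seizure_factor,
                        double period_s, double peak_tod_s, double t0_tod) {
  const int n = phase0.size();
  const int E = edges.nrow();
  const R_xlen_t n_steps = (R_xlen_t) n_steps_d;
  const double two_pi = 2.0 * M_PI;

  std::vector<double> phi(phase0.begin(), phase0.end());
  std::vector<double> omega(n);
  for (int c = 0; c < n; ++c) omega[c] = two_pi * freq_hz[c];

  std::vector<int> ei(E), ej(E);
  std::vector<double> wd(E), wn(E);
  for (int e = 0; e < E; ++e) {
    ei[e] = (int) edges(e, 0);
    ej[e] = (int) edges(e, 1);
    wd[e] = edges(e, 2);
    wn[e] = edges(e, 3);
  }

  R_xlen_t n_kept = 0;
  for (int s = 0; s < seg_len.size(); ++s) n_kept += seg_len[s];
  NumericMatrix x(n_kept, n);

  std::vector<double> dphi(n);
  int seg = 0, n_seg = seg_start.size();
  R_xlen_t out_row = 0;
  int szi = 0, n_sz = sz_start.size();

  for (R_xlen_t step = 0; step < n_steps; ++step) {
    double t = step * dt;

    // record before advancing so sample j sits at time j*dt
    if (seg < n_seg && step >= seg_start[seg]) {
      if (step < (R_xlen_t) seg_start[seg] + seg_len[seg]) {
        for (int c = 0; c < n; ++c) x(out_row, c) = sin(phi[c]);
        ++out_row;
      }
      if (step + 1 >= (R_xlen_t) seg_start[seg] + seg_len[seg]) ++seg;
    }

    // day weight: 1 at peak_tod, 0 half a period away
    double s_day = 0.5 * (1.0 + cos(two_pi * (t0_tod + t - peak_tod_s) / period_s));
    double k = k_low + (k_high - k_low) * s_day;
    while (szi < n_sz && t >= sz_end[szi]) ++szi;
    if (szi < n_sz && t >= sz_start[szi] && t < sz_end[szi]) k *= seizure_factor;

    for (int c = 0; c < n; ++c) dphi[c] = omega[c];
    for (int e = 0; e < E; ++e) {
      double w = k * (s_day * wd[e] + (1.0 - s_day) * wn[e]);
      if (w != 0.0) {
        double d = w * sin(phi[ej[e]] - phi[ei[e]]);
        dphi[ei[e]] += d;
        dphi[ej[e]] -= d;
      }
    }
    for (int c = 0; c < n; ++c) {
      phi[c] += dt * dphi[c];
      if (phi[c] > 1e6 || phi[c] < -1e6)
        phi[c] -= two_pi * std::floor(phi[c] / two_pi);
    }
    if (step % 2000000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["x"] = x,
                      _["phase_end"] = NumericVector(phi.begin(), phi.end()));
}
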