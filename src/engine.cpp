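// Exact event-driven simulation of N pulse-coupled phase neurons with the
// additive nearest-neighbor pair-based STDP rule.
//
// Between firing events phases drift linearly; at each firing of neuron j
// every other neuron i receives an instantaneous phase kick of strength
// g*W(i,j).  For quadratic integrate-and-fire neurons the kick is applied
// exactly through the voltage representation (the arccot update); for a
// tabulated phase response curve the first-order Winfree kick
// phi <- phi + g*W*Z(phi) is used.  Weight updates follow the pair-based
// rule with hard bounds [0,1].

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925286766559;

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// exact QIF phase kick: phi' = 2*arccot(cot(phi/2) - 2*kick/omega),
// arccot taken on (0, pi) so phi' lies in (0, 2*pi)
static inline double qif_kick(double phi, double omega, double kick) {
  if (phi <= 0.0) return phi;       // at reset, PRC vanishes
  double x = 1.0 / std::tan(0.5 * phi) - 2.0 * kick / omega;
  return 2.0 * (M_PI_2 - std::atan(x));
}

// linear interpolation of a tabulated PRC on a grid over [0, 2*pi]
static inline double interp_prc(const double *phases, const double *vals,
                                int n, double phi) {
  if (phi <= phases[0]) return vals[0];
  if (phi >= phases[n - 1]) return vals[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (phases[mid] <= phi) lo = mid; else hi = mid;
  }
  double w = (phi - phases[lo]) / (phases[hi] - phases[lo]);
  return (1.0 - w) * vals[lo] + w * vals[hi];
}

// [[Rcpp::export]]
List sim_network_cpp(NumericVector omega, double g, NumericMatrix W0,
                     double p, double d, double tau_p, double tau_d,
                     bool plastic, NumericVector phi0, double t_max,
                     double conv_tol, double conv_patience,
                     int trace_stride, int max_events, bool record_phases,
                     Nullable<NumericVector> prc_phases_,
                     Nullable<NumericMatrix> prc_values_) {
  const int N = omega.size();
  if (W0.nrow() != N || W0.ncol() != N) stop("weight matrix must be N x N");
  if (phi0.size() != N) stop("phi0 must have length N");

  const bool tabulated = prc_phases_.isNotNull();
  NumericVector prc_phases;
  NumericMatrix prc_values;
  if (tabulated) {
    prc_phases = prc_phases_.get();
    prc_values = prc_values_.get();
    if (prc_values.nrow() != prc_phases.size() || prc_values.ncol() != N)
      stop("PRC table must be length(phases) x N");
  }

  std::vector<double> phi(phi0.begin(), phi0.end());
  NumericMatrix W = clone(W0);
  std::vector<double> last_fire(N, 0.0);
  std::vector<bool> has_fired(N, false);

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<double> trace_t;
  std::vector<double> trace_w;
  std::vector<double> phase_log;
  spike_t.reserve(4096);

  double Tmax_nat = 0.0;
  for (int i = 0; i < N; ++i) {
    if (omega[i] <= 0.0) stop("all natural frequencies must be positive");
    Tmax_nat = std::max(Tmax_nat, TWOPI / omega[i]);
  }

  double t = 0.0, sat_start = -1.0;
  bool converged = false;
  int n_events = 0;

  auto record_trace = [&](double tt) {
    trace_t.push_back(tt);
    for (int jj = 0; jj < N; ++jj)
      for (int ii = 0; ii < N; ++ii) trace_w.push_back(W(ii, jj));
  };
  if (trace_stride > 0) record_trace(0.0);

  while (n_events < max_events) {
    // next firing: smallest time to reach 2*pi, ties to the lowest index
    int j = 0;
    double dt = (TWOPI - phi[0]) / omega[0];
    for (int i = 1; i < N; ++i) {
      double di = (TWOPI - phi[i]) / omega[i];
      if (di < dt) { dt = di; j = i; }
    }
    if (dt < 0.0) dt = 0.0;  // guard against rounding at phi ~ 2*pi
    if (t + dt > t_max) break;
    t += dt;
    for (int i = 0; i < N; ++i) phi[i] += omega[i] * dt;
    phi[j] = TWOPI;

    // zero-delay cascade: a kick that carries a phase to/past 2*pi makes
    // that neuron fire at the same instant, in ascending index order
    std::vector<int> queue(1, j);
    std::vector<bool> queued(N, false);
    queued[j] = true;
    int fired = 0;
    while (!queue.empty()) {
      int f = queue.front();
      queue.erase(queue.begin());
      if (++fired > N) stop("cascade exceeded network size (runaway event)");
      ++n_events;
      spike_t.push_back(t);
      spike_id.push_back(f + 1);
      phi[f] = 0.0;

      for (int i = 0; i < N; ++i) {
        if (i == f) continue;
        double kick = g * W(i, f);
        if (kick > 0.0) {
          if (tabulated) {
            double z = interp_prc(REAL(prc_phases), &prc_values(0, i),
                                  prc_phases.size(), phi[i]);
            phi[i] += kick * z;
          } else {
            phi[i] = qif_kick(phi[i], omega[i], kick);
          }
          if (phi[i] >= TWOPI + TWOPI)
            stop("kick wrapped the phase more than once");
          if (phi[i] >= TWOPI && !queued[i]) {
            queued[i] = true;
            // keep the pending queue in ascending index order
            size_t pos = 0;
            while (pos < queue.size() && queue[pos] < i) ++pos;
            queue.insert(queue.begin() + pos, i);
          }
        }
      }

      if (plastic) {
        for (int i = 0; i < N; ++i) {
          if (i == f || !has_fired[i]) continue;
          double delta = t - last_fire[i];
          if (delta < 0.0) stop("negative spike-time difference");
          W(f, i) = clip01(W(f, i) + p * std::exp(-delta / tau_p));
          W(i, f) = clip01(W(i, f) - d * std::exp(-delta / tau_d));
        }
      }
      last_fire[f] = t;
      has_fired[f] = true;

      if (record_phases)
        for (int i = 0; i < N; ++i) phase_log.push_back(phi[i]);
      if (trace_stride > 0 && n_events % trace_stride == 0) record_trace(t);
    }

    // early stop when every weight has saturated near 0 or 1 and stayed
    // there for conv_patience time units
    if (plastic && conv_patience > 0.0) {
      bool sat = true;
      for (int jj = 0; jj < N && sat; ++jj)
        for (int ii = 0; ii < N; ++ii) {
          if (ii == jj) continue;
          double w = W(ii, jj);
          if (w > conv_tol && w < 1.0 - conv_tol) { sat = false; break; }
        }
      if (sat) {
        if (sat_start < 0.0) sat_start = t;
        else if (t - sat_start >= conv_patience) { converged = true; break; }
      } else {
        sat_start = -1.0;
      }
    }
  }

  if (trace_stride > 0) record_trace(t);

  int ns = spike_t.size();
  NumericMatrix phases_out;
  if (record_phases) {
    phases_out = NumericMatrix(ns, N);
    for (int k = 0; k < ns; ++k)
      for (int i = 0; i < N; ++i) phases_out(k, i) = phase_log[k * N + i];
  }
  int ntr = trace_t.size();
  NumericMatrix trace_W(ntr, N * N);
  for (int k = 0; k < ntr; ++k)
    for (int q = 0; q < N * N; ++q) trace_W(k, q) = trace_w[k * N * N + q];

  return List::create(
      _["spike_t"] = wrap(spike_t), _["spike_id"] = wrap(spike_id),
      _["final_W"] = W, _["trace_t"] = wrap(trace_t), _["trace_W"] = trace_W,
      _["converged"] = converged, _["t_end"] = t, _["n_events"] = n_events,
      _["phases"] = record_phases ? (SEXP)phases_out : R_NilValue,
      _["sat_time"] = sat_start);
}
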