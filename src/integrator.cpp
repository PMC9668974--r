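// Adaptive Dormand-Prince RK45 integrator for the conductance-based neuron
// models, with in-step refinement of membrane-potential maxima (spike times)
// by cubic Hermite interpolation, and threshold/reset handling for the
// quadratic integrate-and-fire voltage equation with finite peak/reset.
//
// Model state layouts:
//   kind 1 (Wang-Buzsaki):  y = (v, h, n); params = (Cm, gK, gNa, gL,
//       vK, vNa, vL, phi, I)
//   kind 2 (Morris-Lecar):  y = (v, n); params = (Cm, gCa, gK, gL,
//       vCa, vK, vL, v1, v2, v3, v4, I0, phi, eta)
//   kind 3 (QIF voltage):   y = (v); params = (eta, v_peak, v_reset)

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int MAXDIM = 3;

// x / (1 - exp(-0.1 x)) with a series fallback at the removable singularity
static inline double lin_over_expm1(double x) {
  if (std::fabs(x) < 1e-4) return 10.0 + 0.5 * x;
  return x / (-std::expm1(-0.1 * x));
}

struct NeuronModel {
  int kind;
  std::vector<double> p;
  int dim() const { return kind == 1 ? 3 : (kind == 2 ? 2 : 1); }
  double spike_threshold() const {
    return kind == 1 ? 0.0 : (kind == 2 ? 10.0 : 0.0);
  }

  void rhs(const double *y, double *f) const {
    if (kind == 1) {
      const double Cm = p[0], gK = p[1], gNa = p[2], gL = p[3];
      const double vK = p[4], vNa = p[5], vL = p[6], phi = p[7], I = p[8];
      const double v = y[0], h = y[1], n = y[2];
      const double am = 0.1 * lin_over_expm1(v + 35.0);
      const double bm = 4.0 * std::exp(-(v + 60.0) / 18.0);
      const double minf = am / (am + bm);
      const double ah = 0.07 * std::exp(-(v + 58.0) / 20.0);
      const double bh = 1.0 / (1.0 + std::exp(-0.1 * (v + 28.0)));
      const double an = 0.01 * lin_over_expm1(v + 34.0);
      const double bn = 0.125 * std::exp(-(v + 44.0) / 80.0);
      const double n4 = n * n * n * n;
      f[0] = (-gK * n4 * (v - vK) - gNa * minf * minf * minf * h * (v - vNa)
              - gL * (v - vL) + I) / Cm;
      f[1] = phi * (ah * (1.0 - h) - bh * h);
      f[2] = phi * (an * (1.0 - n) - bn * n);
    } else if (kind == 2) {
      const double Cm = p[0], gCa = p[1], gK = p[2], gL = p[3];
      const double vCa = p[4], vK = p[5], vL = p[6];
      const double v1 = p[7], v2 = p[8], v3 = p[9], v4 = p[10];
      const double I0 = p[11], phi = p[12], eta = p[13];
      const double v = y[0], n = y[1];
      const double minf = 0.5 * (1.0 + std::tanh((v - v1) / v2));
      const double ninf = 0.5 * (1.0 + std::tanh((v - v3) / v4));
      const double inv_taun = std::cosh((v - v3) / (2.0 * v4));
      f[0] = eta * (-gCa * minf * (v - vCa) - gK * n * (v - vK)
                    - gL * (v - vL) + I0) / Cm;
      f[1] = eta * phi * (ninf - n) * inv_taun;
    } else {
      f[0] = y[0] * y[0] + p[0];
    }
  }
};

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

struct Stepper {
  const NeuronModel &m;
  int dim;
  double rtol, atol;
  double y[MAXDIM], f0[MAXDIM];      // current state and derivative
  double ynew[MAXDIM], fnew[MAXDIM]; // proposed state and derivative
  double t, h;
  long n_steps;

  Stepper(const NeuronModel &mod, const double *y0, double t0,
          double rtol_, double atol_)
      : m(mod), dim(mod.dim()), rtol(rtol_), atol(atol_), t(t0), h(1e-3),
        n_steps(0) {
    for (int i = 0; i < dim; ++i) y[i] = y0[i];
    m.rhs(y, f0);
  }

  // attempt steps until one is accepted; on return [t, t+h_used] holds
  // (y, f0) -> (ynew, fnew); caller must call advance() to commit
  double h_used;
  void step(double hmax) {
    double k2[MAXDIM], k3[MAXDIM], k4[MAXDIM], k5[MAXDIM], k6[MAXDIM],
        ytmp[MAXDIM], err[MAXDIM];
    for (;;) {
      if (++n_steps > 200000000L) stop("integrator exceeded step limit");
      double hh = std::min(h, hmax);
      for (int i = 0; i < dim; ++i) ytmp[i] = y[i] + hh * a21 * f0[i];
      m.rhs(ytmp, k2);
      for (int i = 0; i < dim; ++i)
        ytmp[i] = y[i] + hh * (a31 * f0[i] + a32 * k2[i]);
      m.rhs(ytmp, k3);
      for (int i = 0; i < dim; ++i)
        ytmp[i] = y[i] + hh * (a41 * f0[i] + a42 * k2[i] + a43 * k3[i]);
      m.rhs(ytmp, k4);
      for (int i = 0; i < dim; ++i)
        ytmp[i] = y[i] + hh * (a51 * f0[i] + a52 * k2[i] + a53 * k3[i] +
                               a54 * k4[i]);
      m.rhs(ytmp, k5);
      for (int i = 0; i < dim; ++i)
        ytmp[i] = y[i] + hh * (a61 * f0[i] + a62 * k2[i] + a63 * k3[i] +
                               a64 * k4[i] + a65 * k5[i]);
      m.rhs(ytmp, k6);
      for (int i = 0; i < dim; ++i)
        ynew[i] = y[i] + hh * (b1 * f0[i] + b3 * k3[i] + b4 * k4[i] +
                               b5 * k5[i] + b6 * k6[i]);
      m.rhs(ynew, fnew);
      for (int i = 0; i < dim; ++i)
        err[i] = hh * (e1 * f0[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                       e6 * k6[i] + e7 * fnew[i]);
      double en = 0.0;
      for (int i = 0; i < dim; ++i) {
        double sc = atol + rtol * std::max(std::fabs(y[i]),
                                           std::fabs(ynew[i]));
        double r = err[i] / sc;
        en += r * r;
      }
      en = std::sqrt(en / dim);
      if (!std::isfinite(en)) { h = hh * 0.1; continue; }
      if (en <= 1.0) {
        h_used = hh;
        double fac = (en == 0.0) ? 6.0
                                 : std::min(6.0, std::max(0.2, 0.9 * std::pow(en, -0.2)));
        h = hh * fac;
        return;
      }
      h = hh * std::max(0.2, 0.9 * std::pow(en, -0.2));
    }
  }

  void advance() {
    t += h_used;
    for (int i = 0; i < dim; ++i) { y[i] = ynew[i]; f0[i] = fnew[i]; }
    if (!std::isfinite(y[0])) stop("integration blew up (non-finite state)");
  }

  // cubic Hermite interpolation of component i at fraction s of [t, t+h_used]
  double hermite(int i, double s) const {
    double s2 = s * s, s3 = s2 * s;
    return (2 * s3 - 3 * s2 + 1) * y[i] + (s3 - 2 * s2 + s) * h_used * f0[i] +
           (-2 * s3 + 3 * s2) * ynew[i] + (s3 - s2) * h_used * fnew[i];
  }
  double hermite_deriv(int i, double s) const {
    double s2 = s * s;
    return ((6 * s2 - 6 * s) * y[i] + (3 * s2 - 4 * s + 1) * h_used * f0[i] +
            (-6 * s2 + 6 * s) * ynew[i] + (3 * s2 - 2 * s) * h_used * fnew[i]) /
           h_used;
  }
};

static NeuronModel make_model(int kind, const NumericVector &params) {
  NeuronModel m;
  m.kind = kind;
  m.p = as<std::vector<double> >(params);
  int need = kind == 1 ? 9 : (kind == 2 ? 14 : 3);
  if ((int)m.p.size() != need) stop("wrong parameter vector length");
  return m;
}

// locate the interior maximum of v within the accepted step, if any;
// returns s in (0,1] or -1
static double find_vmax_s(const Stepper &st) {
  // v' changes sign from + to - somewhere in the step
  double d0 = st.f0[0], d1 = st.fnew[0];
  if (!(d0 > 0.0 && d1 <= 0.0)) return -1.0;
  // Hermite derivative is quadratic in s; bisect on it
  double lo = 0.0, hi = 1.0;
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (lo + hi);
    if (st.hermite_deriv(0, mid) > 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// Integrate and collect spike times (membrane-potential maxima above the
// model threshold; for QIF, upward crossings of v_peak followed by reset).
// [[Rcpp::export]]
List ode_spikes_cpp(int kind, NumericVector params, NumericVector y0,
                    double t0, double t_end, double rtol, double atol,
                    int max_spikes) {
  NeuronModel m = make_model(kind, params);
  int dim = m.dim();
  if (y0.size() != dim) stop("state vector has wrong length");
  std::vector<double> sp_t;
  std::vector<double> sp_state; // states at spike maxima, row-major
  Stepper st(m, REAL(y0), t0, rtol, atol);

  if (kind == 3 && st.y[0] >= m.p[1]) { // already at/above peak
    sp_t.push_back(t0);
    sp_state.push_back(m.p[1]);
    st.y[0] = m.p[2];
    m.rhs(st.y, st.f0);
  }

  while (st.t < t_end) {
    st.step(t_end - st.t);
    if (kind == 3) {
      double vp = m.p[1];
      if (st.ynew[0] >= vp) {
        // find first upward crossing of vp by bisection on the Hermite poly
        double lo = 0.0, hi = 1.0;
        for (int it = 0; it < 80; ++it) {
          double mid = 0.5 * (lo + hi);
          if (st.hermite(0, mid) < vp) lo = mid; else hi = mid;
        }
        double s = 0.5 * (lo + hi);
        double tsp = st.t + s * st.h_used;
        sp_t.push_back(tsp);
        sp_state.push_back(vp);
        if ((int)sp_t.size() >= max_spikes) break;
        // reset and continue from the crossing time
        st.t = tsp;
        st.y[0] = m.p[2];
        m.rhs(st.y, st.f0);
        st.h = std::min(st.h, 1e-3);
        continue;
      }
      st.advance();
    } else {
      double s = find_vmax_s(st);
      if (s > 0.0) {
        double vmax = st.hermite(0, s);
        if (vmax >= m.spike_threshold()) {
          sp_t.push_back(st.t + s * st.h_used);
          for (int i = 0; i < dim; ++i) sp_state.push_back(st.hermite(i, s));
          if ((int)sp_t.size() >= max_spikes) { st.advance(); break; }
        }
      }
      st.advance();
    }
  }

  int ns = sp_t.size();
  NumericMatrix states(ns, dim);
  for (int k = 0; k < ns; ++k)
    for (int i = 0; i < dim; ++i) states(k, i) = sp_state[k * dim + i];
  NumericVector yend(dim);
  for (int i = 0; i < dim; ++i) yend[i] = st.y[i];
  return List::create(_["spike_times"] = wrap(sp_t),
                      _["spike_states"] = states,
                      _["y_end"] = yend, _["t_end"] = st.t);
}

// Integrate and return states at the requested output times (steps are
// clipped to land exactly on each output time).
// [[Rcpp::export]]
NumericMatrix ode_states_cpp(int kind, NumericVector params, NumericVector y0,
                             double t0, NumericVector times, double rtol,
                             double atol) {
  NeuronModel m = make_model(kind, params);
  int dim = m.dim();
  if (y0.size() != dim) stop("state vector has wrong length");
  int nt = times.size();
  NumericMatrix out(nt, dim);
  Stepper st(m, REAL(y0), t0, rtol, atol);
  if (kind == 3 && st.y[0] >= m.p[1]) { // start at/above peak: reset first
    st.y[0] = m.p[2];
    m.rhs(st.y, st.f0);
  }
  for (int k = 0; k < nt; ++k) {
    double target = times[k];
    if (target < st.t - 1e-12) stop("output times must be nondecreasing");
    while (st.t < target) {
      st.step(target - st.t);
      if (kind == 3 && st.ynew[0] >= m.p[1]) {
        double vp = m.p[1];
        double lo = 0.0, hi = 1.0;
        for (int it = 0; it < 80; ++it) {
          double mid = 0.5 * (lo + hi);
          if (st.hermite(0, mid) < vp) lo = mid; else hi = mid;
        }
        st.t += 0.5 * (lo + hi) * st.h_used;
        st.y[0] = m.p[2];
        m.rhs(st.y, st.f0);
        st.h = std::min(st.h, 1e-3);
        continue;
      }
      st.advance();
    }
    for (int i = 0; i < dim; ++i) out(k, i) = st.y[i];
  }
  return out;
}
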