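#include <Rcpp.h>
using namespace Rcpp;

// Cross-bridge force state F_xb and rested-state (thixotropic) stiffness
// fraction R, integrated at the sampling rate (forward Euler; all rates
// are slow relative to dt = 0.5 ms):
//   dF_xb/dt = k_xb * (1 + eta * R) * v - |v| * F_xb / s0 - F_xb / tau
//   dR/dt    = (1 - R) / tau_rec      - |v| * R / s_r
// R builds toward 1 during quiescence (time constant tau_rec) and is
// destroyed by movement over the slip travel s_r, carrying the long-range
// history (first-stretch enhancement) that the fast slip element forgets.
// [[Rcpp::export(name = ".simulate_xb")]]
NumericVector simulate_xb(NumericVector v, double dt, double k_xb,
                          double s0, double tau, double eta, double s_r,
                          double tau_rec) {
  const int n = v.size();
  NumericVector f(n);
  double fx = 0.0;
  double R = 1.0; // trials begin after prolonged quiescence
  for (int i = 0; i < n; ++i) {
    double av = std::abs(v[i]);
    double dfx = k_xb * (1.0 + eta * R) * v[i] - av * fx / s0 - fx / tau;
    double dR = (1.0 - R) / tau_rec - av * R / s_r;
    fx += dt * dfx;
    R += dt * dR;
    if (R < 0.0) R = 0.0;
    if (R > 1.0) R = 1.0;
    if (!std::isfinite(fx)) stop("force integration diverged");
    f[i] = fx;
  }
  return f;
}

// Rate-sampled spike generator: spike i satisfies
//   (t_i - t_{i-1}) * r(t_i) = h_i
// with r piecewise linear on the sampling grid. With all thresholds
// h_i = 1 (thresholds empty) the recorded instantaneous firing rate 1/ISI
// samples the rate exactly at each spike (deterministic mode); with
// gamma-distributed unit-mean h_i it is the stochastic twin (for a
// constant rate and exponential h this is exactly a Poisson process).
// The first spike is seeded where the integral of r first reaches h_1.
// Rates are in events/s; t[k] = t0 + k * dt.
// [[Rcpp::export(name = ".spikes_rate_sampled")]]
NumericVector spikes_rate_sampled(NumericVector r, double dt, double t0,
                                  NumericVector thresholds) {
  const int n = r.size();
  const int nth = thresholds.size();
  std::vector<double> out;
  if (n < 2) return NumericVector(0);
  size_t spike_i = 0;
  auto thresh = [&](size_t i) { return nth == 0 ? 1.0 : (i < (size_t)nth ? thresholds[i] : NA_REAL); };

  // --- first spike: area crossing, exact on linear segments
  double h1 = thresh(0);
  if (!std::isfinite(h1)) return NumericVector(0);
  double cum = 0.0;
  double t_prev = NA_REAL;
  for (int k = 1; k < n; ++k) {
    double seg = 0.5 * (r[k - 1] + r[k]) * dt;
    if (cum + seg >= h1) {
      double need = h1 - cum;
      double s = (r[k] - r[k - 1]) / dt;
      double a = 0.5 * s, b = r[k - 1], c = -need;
      double u;
      if (std::abs(a) < 1e-12) {
        u = b > 0 ? need / b : dt;
      } else {
        double disc = b * b - 4 * a * c;
        disc = disc > 0 ? std::sqrt(disc) : 0.0;
        u = (-b + disc) / (2 * a);
        if (!(u >= 0.0 && u <= dt)) u = (-b - disc) / (2 * a);
      }
      if (!(u >= 0.0)) u = 0.0;
      if (u > dt) u = dt;
      t_prev = t0 + (k - 1) * dt + u;
      out.push_back(t_prev);
      ++spike_i;
      break;
    }
    cum += seg;
  }
  if (!std::isfinite(t_prev)) return NumericVector(0);

  // --- subsequent spikes: self-consistent ISI on the linear segments
  int k = (int)std::ceil((t_prev - t0) / dt);
  if (k < 1) k = 1;
  double hi = thresh(spike_i);
  while (k < n && std::isfinite(hi)) {
    double tk = t0 + k * dt;
    double h = (tk - t_prev) * r[k] - hi;
    if (h >= 0.0) {
      double t_lo = t0 + (k - 1) * dt;
      double base = t_lo > t_prev ? t_lo : t_prev;
      double s = (r[k] - r[k - 1]) / dt;
      double r_base = r[k - 1] + s * (base - t_lo);
      double off = base - t_prev;
      double umax = tk - base;
      // (off + u) * (r_base + s*u) = hi
      double A = s, B = r_base + s * off, C = off * r_base - hi;
      double u;
      if (std::abs(A) < 1e-12) {
        u = B > 0 ? -C / B : umax;
      } else {
        double disc = B * B - 4 * A * C;
        disc = disc > 0 ? std::sqrt(disc) : 0.0;
        double u1 = (-B + disc) / (2 * A);
        double u2 = (-B - disc) / (2 * A);
        bool ok1 = u1 >= -1e-12 && u1 <= umax + 1e-12;
        bool ok2 = u2 >= -1e-12 && u2 <= umax + 1e-12;
        if (ok1 && ok2)
          u = u1 < u2 ? u1 : u2;
        else if (ok1)
          u = u1;
        else if (ok2)
          u = u2;
        else
          u = umax;
      }
      if (u < 0) u = 0;
      if (u > umax) u = umax;
      double t_new = base + u;
      if (t_new <= t_prev) t_new = t_prev + 1e-9;
      out.push_back(t_new);
      t_prev = t_new;
      ++spike_i;
      hi = thresh(spike_i);
      k = (int)std::ceil((t_prev - t0) / dt);
      if (k < 1) k = 1;
      if (t_prev >= t0 + (n - 1) * dt) break;
    } else {
      ++k;
    }
  }
  return NumericVector(out.begin(), out.end());
}
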