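#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state initiation-inactivation-repopulation dynamics between treatment
// pulses.  State y = (n, m): normal and premalignant cell counts.
//
//   dn/dt = lam*n*(1 - n/N) - (kc(t) + mc)*n
//   dm/dt = r*lam*m*(1 - n/N) - kc(t)*m + mc*n
//
// kc(t) is the chemotherapy kill rate, summed over active cycles i:
//   kc(t) = kill0 * exp(-alpha_d * (t - c_i)),  c_i <= t < c_i + window
// mc is the chemotherapy mutation flux rate (constant while a cycle is
// active); the flux leaves n and enters m.  Radiotherapy pulses are applied
// as impulses by the R driver and never appear here, so the right-hand side
// is smooth on every segment the driver requests.

struct IirPars {
  double lam, r, N;
  const double *cyc;
  int ncyc;
  double window, kill0, mut0, alpha_d;
};

static inline void rhs(double t, const double y[2], double dy[2],
                       const IirPars &p) {
  double kc = 0.0, mc = 0.0;
  for (int i = 0; i < p.ncyc; ++i) {
    double s = t - p.cyc[i];
    if (s >= 0.0 && s < p.window) {
      kc += p.kill0 * std::exp(-p.alpha_d * s);
      mc += p.mut0;
    }
  }
  double gro = 1.0 - y[0] / p.N;
  dy[0] = p.lam * y[0] * gro - (kc + mc) * y[0];
  dy[1] = p.r * p.lam * y[1] * gro - kc * y[1] + mc * y[0];
}

// Dormand-Prince 5(4) adaptive step integrator for the 2-state system.
static void dopri5(double t0, double t1, double y[2], const IirPars &p,
                   double rtol, double atol) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
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
  static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                      e3 = 500.0 / 1113 - 7571.0 / 16695,
                      e4 = 125.0 / 192 - 393.0 / 640,
                      e5 = -2187.0 / 6784 + 92097.0 / 339200,
                      e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

  double span = t1 - t0;
  if (span <= 0.0) return;
  double h = span / 20.0;
  if (h > 0.5) h = 0.5;
  double t = t0;
  int steps = 0;
  const int max_steps = 1000000;
  double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], k7[2], yt[2], y5[2];

  rhs(t, y, k1, p);
  while (t < t1) {
    if (++steps > max_steps)
      stop("integration failure: step limit exceeded (tolerance not met)");
    if (t + h > t1) h = t1 - t;

    for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * a21 * k1[i];
    rhs(t + c2 * h, yt, k2, p);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(t + c3 * h, yt, k3, p);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(t + c4 * h, yt, k4, p);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    rhs(t + c5 * h, yt, k5, p);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    rhs(t + h, yt, k6, p);
    for (int i = 0; i < 2; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    rhs(t + h, y5, k7, p);

    double err = 0.0;
    for (int i = 0; i < 2; ++i) {
      double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                      e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double q = e / sc;
      err += q * q;
    }
    err = std::sqrt(err / 2.0);

    if (err <= 1.0) {
      t += h;
      y[0] = y5[0];
      y[1] = y5[1];
      k1[0] = k7[0];
      k1[1] = k7[1];  // FSAL
      if (!std::isfinite(y[0]) || !std::isfinite(y[1]))
        stop("integration failure: non-finite state");
    }
    double fac = 0.9 * std::pow(err > 1e-10 ? err : 1e-10, -0.2);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-14) stop("integration failure: step size underflow");
  }
}

//' @keywords internal
// [[Rcpp::export(name = ".iir_segment")]]
NumericMatrix iir_segment(NumericVector y0, NumericVector times, double lam,
                          double r, double N, NumericVector cycle_starts,
                          double window, double kill0, double mut0,
                          double alpha_d, double rtol, double atol) {
  if (y0.size() != 2) stop("y0 must have length 2");
  if (times.size() < 2) stop("times must have length >= 2");
  IirPars p;
  p.lam = lam;
  p.r = r;
  p.N = N;
  p.cyc = cycle_starts.size() ? &cycle_starts[0] : NULL;
  p.ncyc = cycle_starts.size();
  p.window = window;
  p.kill0 = kill0;
  p.mut0 = mut0;
  p.alpha_d = alpha_d;

  double y[2] = {y0[0], y0[1]};
  NumericMatrix out(times.size(), 2);
  out(0, 0) = y[0];
  out(0, 1) = y[1];
  for (int j = 1; j < times.size(); ++j) {
    if (times[j] < times[j - 1]) stop("times must be non-decreasing");
    dopri5(times[j - 1], times[j], y, p, rtol, atol);
    out(j, 0) = y[0];
    out(j, 1) = y[1];
  }
  return out;
}
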