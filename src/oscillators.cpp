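#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of the three delay-coupled noisy phase
// oscillators: stimulus S (deterministic, exactly linear phase), attention A
// and motor M. Natural frequencies are in Hz (converted to rad/s here),
// couplings K in rad/s, noise intensities D in rad^2/s. Delays are supplied
// as whole numbers of dt steps; delayed phases before t = 0 come from
// backward extrapolation at each oscillator's natural frequency from its
// initial phase. Two standard normals are consumed per step (A then M) from
// R's RNG, so trajectories are reproducible under set.seed().
//
// theta(t+dt) = theta(t) + dt * (2*pi*omega + sum K * sin(theta_src(t - tau)
//               - theta(t))) + sqrt(2*D*dt) * z

// [[Rcpp::export]]
List simulate_phases_cpp(double omega_s, double omega_a, double omega_m,
                         double k_as, double k_am, double k_ma, double k_ms,
                         int lag_as, int lag_am, int lag_ma, int lag_ms,
                         double d_a, double d_m,
                         double dt, int n_steps,
                         double theta_s0, double theta_a0, double theta_m0) {
  const double two_pi = 2.0 * M_PI;
  const double ws = two_pi * omega_s;
  const double wa = two_pi * omega_a;
  const double wm = two_pi * omega_m;
  const double sig_a = std::sqrt(2.0 * d_a * dt);
  const double sig_m = std::sqrt(2.0 * d_m * dt);

  NumericVector th_s(n_steps + 1), th_a(n_steps + 1), th_m(n_steps + 1);
  th_s[0] = theta_s0;
  th_a[0] = theta_a0;
  th_m[0] = theta_m0;

  // delayed phase lookup with pre-history extrapolated backwards at the
  // natural frequency
  auto delayed = [&](const NumericVector& th, double w, double th0,
                     int i, int lag) -> double {
    int j = i - lag;
    if (j >= 0) return th[j];
    return th0 + w * (j * dt);
  };

  for (int i = 0; i < n_steps; ++i) {
    double t_next = (i + 1) * dt;
    th_s[i + 1] = theta_s0 + ws * t_next;  // exact: no noise, no coupling on S

    double s_for_a = delayed(th_s, ws, theta_s0, i, lag_as);
    double m_for_a = delayed(th_m, wm, theta_m0, i, lag_am);
    double a_for_m = delayed(th_a, wa, theta_a0, i, lag_ma);
    double s_for_m = delayed(th_s, ws, theta_s0, i, lag_ms);

    double za = norm_rand();
    double zm = norm_rand();

    th_a[i + 1] = th_a[i] + dt * (wa
      + k_am * std::sin(m_for_a - th_a[i])
      + k_as * std::sin(s_for_a - th_a[i]))
      + sig_a * za;

    th_m[i + 1] = th_m[i] + dt * (wm
      + k_ma * std::sin(a_for_m - th_m[i])
      + k_ms * std::sin(s_for_m - th_m[i]))
      + sig_m * zm;
  }

  return List::create(_["theta_s"] = th_s,
                      _["theta_a"] = th_a,
                      _["theta_m"] = th_m);
}

// Modulus of the time-averaged unit phasor of the phase difference.
// [[Rcpp::export]]
double plv_cpp(NumericVector theta_x, NumericVector theta_y) {
  int n = theta_x.size();
  double sc = 0.0, ss = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = theta_x[i] - theta_y[i];
    sc += std::cos(d);
    ss += std::sin(d);
  }
  return std::sqrt(sc * sc + ss * ss) / n;
}
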