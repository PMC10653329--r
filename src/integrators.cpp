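#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Poisson-kernel pulse h(x, rho) = (1 - rho) e^{ix} / (1 - rho e^{ix})
static inline std::complex<double> pulse(double x, double rho) {
  std::complex<double> eix(std::cos(x), std::sin(x));
  return (1.0 - rho) * eix / (1.0 - rho * eix);
}

struct Deriv { double dphi, domega; };

// Right-hand side of the context-dependent model in explicit (phi, omega)
// form. The relative-phase rate on the bias term is substituted by the
// exact identity psi_dot = dphi/dt - omega0.
static inline Deriv ctx_rhs(double t, double phi, double omega,
                            double omega0, double c, double gamma,
                            double lambda, double Delta, double psi_theta,
                            double rho) {
  const double theta = omega0 * t;
  const std::complex<double> prod = pulse(theta, rho) * pulse(-phi, rho);
  const double f = prod.imag();
  const double psi = phi - theta;
  const double g = (psi <= psi_theta) ? 1.0 : 1.0 - std::abs(prod);
  Deriv d;
  d.dphi = omega + c * f;
  d.domega = gamma * f - lambda * g * (d.dphi - omega0 - Delta);
  return d;
}

// Fixed-step RK4 for the context-dependent phasing model. The intentional
// bias strength lambda steps from lambda_pre to lambda_post at cue_time,
// which the caller aligns with the time grid. lambda is held constant over
// each step (the value at the step start), so the discontinuity sits
// exactly on a step boundary and the integrator keeps its full order on
// both sides.
// [[Rcpp::export]]
List context_rk4(double omega0, double c, double gamma,
                 double lambda_pre, double lambda_post, double Delta,
                 double psi_theta, double rho, double cue_time,
                 double duration, double dt) {
  const int n = (int)std::llround(duration / dt) + 1;
  NumericVector t(n), phi(n), omega(n);
  phi[0] = 0.0;
  omega[0] = omega0;
  const double eps = 1e-12;
  for (int i = 0; i < n; ++i) t[i] = i * dt;
  for (int i = 0; i < n - 1; ++i) {
    const double ti = t[i];
    const double lam = (ti >= cue_time - eps) ? lambda_post : lambda_pre;
    const Deriv k1 = ctx_rhs(ti, phi[i], omega[i],
                             omega0, c, gamma, lam, Delta, psi_theta, rho);
    const Deriv k2 = ctx_rhs(ti + 0.5 * dt, phi[i] + 0.5 * dt * k1.dphi,
                             omega[i] + 0.5 * dt * k1.domega,
                             omega0, c, gamma, lam, Delta, psi_theta, rho);
    const Deriv k3 = ctx_rhs(ti + 0.5 * dt, phi[i] + 0.5 * dt * k2.dphi,
                             omega[i] + 0.5 * dt * k2.domega,
                             omega0, c, gamma, lam, Delta, psi_theta, rho);
    const Deriv k4 = ctx_rhs(ti + dt, phi[i] + dt * k3.dphi,
                             omega[i] + dt * k3.domega,
                             omega0, c, gamma, lam, Delta, psi_theta, rho);
    phi[i + 1] = phi[i] + dt / 6.0 * (k1.dphi + 2.0 * k2.dphi + 2.0 * k3.dphi + k4.dphi);
    omega[i + 1] = omega[i] + dt / 6.0 * (k1.domega + 2.0 * k2.domega + 2.0 * k3.domega + k4.domega);
  }
  return List::create(_["t"] = t, _["phi"] = phi, _["omega"] = omega);
}

// Fixed-step RK4 for the sine-coupled oscillator with a fixed natural
// frequency: dphi/dt = omega(t) + c sin(omega0 t - phi), where omega steps
// from omega0 to omega0 + delta_omega at detune_at. As above, the natural
// frequency is held constant over each step so the jump lands on a step
// boundary.
// [[Rcpp::export]]
List fixed_rk4(double omega0, double c, double delta_omega,
               double detune_at, double duration, double dt) {
  const int n = (int)std::llround(duration / dt) + 1;
  NumericVector t(n), phi(n), omega(n);
  phi[0] = 0.0;
  const double eps = 1e-12;
  for (int i = 0; i < n; ++i) {
    t[i] = i * dt;
    omega[i] = (t[i] >= detune_at - eps) ? omega0 + delta_omega : omega0;
  }
  auto rhs = [&](double tt, double p, double w) {
    return w + c * std::sin(omega0 * tt - p);
  };
  for (int i = 0; i < n - 1; ++i) {
    const double ti = t[i];
    const double w = omega[i];
    const double k1 = rhs(ti, phi[i], w);
    const double k2 = rhs(ti + 0.5 * dt, phi[i] + 0.5 * dt * k1, w);
    const double k3 = rhs(ti + 0.5 * dt, phi[i] + 0.5 * dt * k2, w);
    const double k4 = rhs(ti + dt, phi[i] + dt * k3, w);
    phi[i + 1] = phi[i] + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }
  return List::create(_["t"] = t, _["phi"] = phi, _["omega"] = omega);
}
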