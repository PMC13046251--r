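#include <Rcpp.h>
using namespace Rcpp;

// Kuramoto-Sakaguchi vector field with a two-community coupling topology,
// evaluated through per-community mean phasors (O(C) per call instead of
// O(C^2)).  Coupling K_ij = K within a community, r*K across communities.
//
// Effective natural frequency at time t:
//   om_i(t) = omega_i + m(t) * (omega_target - omega_i) + amp(t) * detune_i(t)
// m(t) is the ictal entrainment schedule, detune the slow frequency wander.
static void kuramoto_deriv(const std::vector<double> &theta,
                           const std::vector<double> &om_eff,
                           const std::vector<int> &community,
                           double K, double r, double alpha,
                           std::vector<double> &dtheta) {
  const int C = theta.size();
  double c0 = 0.0, s0 = 0.0, c1 = 0.0, s1 = 0.0;
  for (int i = 0; i < C; ++i) {
    const double ci = std::cos(theta[i]), si = std::sin(theta[i]);
    if (community[i] == 0) { c0 += ci; s0 += si; } else { c1 += ci; s1 += si; }
  }
  for (int i = 0; i < C; ++i) {
    double cs, ss; // coupling-weighted sum of e^{i theta_j}
    if (community[i] == 0) { cs = K * c0 + r * K * c1; ss = K * s0 + r * K * s1; }
    else                   { cs = K * c1 + r * K * c0; ss = K * s1 + r * K * s0; }
    // Im( e^{-i(theta_i + alpha)} * (cs + i ss) )
    const double phi = theta[i] + alpha;
    dtheta[i] = om_eff[i] + (ss * std::cos(phi) - cs * std::sin(phi)) / C;
  }
}

// [[Rcpp::export(name = ".rk4_kuramoto")]]
NumericMatrix rk4_kuramoto(NumericVector theta0, NumericVector omega,
                           IntegerVector community, double alpha, double dt,
                           int nsteps, NumericVector K_t, NumericVector r_t,
                           NumericVector m_t, double omega_target,
                           NumericVector amp_t, NumericMatrix detune,
                           int detune_every) {
  const int C = theta0.size();
  if (omega.size() != C || community.size() != C)
    stop("omega/community length must match theta0");
  if (K_t.size() != nsteps || r_t.size() != nsteps || m_t.size() != nsteps ||
      amp_t.size() != nsteps)
    stop("schedule vectors must have length nsteps");
  if (detune.ncol() != C) stop("detune must have C columns");

  NumericMatrix out(nsteps + 1, C);
  std::vector<double> th(C), om_eff(C), k1(C), k2(C), k3(C), k4(C), tmp(C);
  for (int i = 0; i < C; ++i) { th[i] = theta0[i]; out(0, i) = theta0[i]; }
  std::vector<int> comm(C);
  for (int i = 0; i < C; ++i) comm[i] = community[i];
  const int nblocks = detune.nrow();

  for (int s = 0; s < nsteps; ++s) {
    const double K = K_t[s], r = r_t[s], m = m_t[s], amp = amp_t[s];
    int b = (detune_every > 0) ? s / detune_every : 0;
    if (b >= nblocks) b = nblocks - 1;
    for (int i = 0; i < C; ++i)
      om_eff[i] = omega[i] + m * (omega_target - omega[i]) +
                  (nblocks > 0 ? amp * detune(b, i) : 0.0);

    kuramoto_deriv(th, om_eff, comm, K, r, alpha, k1);
    for (int i = 0; i < C; ++i) tmp[i] = th[i] + 0.5 * dt * k1[i];
    kuramoto_deriv(tmp, om_eff, comm, K, r, alpha, k2);
    for (int i = 0; i < C; ++i) tmp[i] = th[i] + 0.5 * dt * k2[i];
    kuramoto_deriv(tmp, om_eff, comm, K, r, alpha, k3);
    for (int i = 0; i < C; ++i) tmp[i] = th[i] + dt * k3[i];
    kuramoto_deriv(tmp, om_eff, comm, K, r, alpha, k4);
    for (int i = 0; i < C; ++i) {
      th[i] += dt * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]) / 6.0;
      out(s + 1, i) = th[i];
    }
  }
  // wrap to (-pi, pi]
  const double twopi = 2.0 * M_PI;
  for (int s = 0; s <= nsteps; ++s)
    for (int i = 0; i < C; ++i) {
      const double x = out(s, i) + M_PI;
      double w = x - twopi * std::floor(x / twopi);
      out(s, i) = (w == 0.0) ? M_PI : w - M_PI;
    }
  return out;
}
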