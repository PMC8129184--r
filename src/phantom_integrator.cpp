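// Semi-implicit time integrator for the desk-scale spring-network phantom.
//
// Interior nodes carry lumped masses and are connected by springs whose
// axial force follows the Ogden simple-shear nominal stress law passed
// through the QLV hereditary integral (recursive exponential update, one
// internal variable per spring per Prony term). Shell anchor nodes follow
// the prescribed rigid rotation exactly. Units: mm, ms (time histories),
// kPa, kg; forces in mN so that accelerations come out in mm/s^2.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void rot_matrix(int axis, double th, double R[3][3]) {
  double c = std::cos(th), s = std::sin(th);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[i][j] = (i == j) ? 1.0 : 0.0;
  int a = (axis + 1) % 3, b = (axis + 2) % 3;
  R[a][a] = c; R[a][b] = -s; R[b][a] = s; R[b][b] = c;
}

// [[Rcpp::export]]
List phantom_integrate_cpp(NumericMatrix X0,       // n_tot x 3 rest positions (mm, centered)
                           int n_int,              // interior nodes are rows 0..n_int-1
                           NumericVector mass,     // kg per interior node
                           IntegerMatrix springs,  // m x 2, 0-based node ids
                           NumericVector rest_len, // mm
                           NumericVector coef,     // effective area per spring, mm^2
                           NumericVector mu,       // kPa per spring
                           double alpha,
                           NumericVector ghat,     // relaxation coefficients (may be empty)
                           NumericVector tau_ms,
                           double ghat_inf,
                           int axis,               // 0 = x (coronal), 1 = y, 2 = z
                           NumericVector theta,    // rotation angle per step, length n_steps + 1
                           double dt_ms,
                           int out_every,
                           IntegerVector receivers, // 0-based interior node ids to record
                           double damping_per_s,
                           double blowup_limit_mm) {
  const int n_tot = X0.nrow(), m = springs.nrow(), K = ghat.size();
  const int n_steps = theta.size() - 1;
  const double dt_s = dt_ms * 1e-3;
  const int n_rec = receivers.size();
  const int n_out = n_steps / out_every + 1;

  std::vector<double> x(3 * n_tot), v(3 * n_int, 0.0), F(3 * n_int, 0.0);
  for (int i = 0; i < n_tot; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = X0(i, d);

  std::vector<double> Te_prev(m, 0.0), h(m * K, 0.0);
  std::vector<double> ek(K), ak(K);
  for (int k = 0; k < K; ++k) {
    ek[k] = std::exp(-dt_ms / tau_ms[k]);
    ak[k] = ghat[k] * (tau_ms[k] / dt_ms) * (1.0 - ek[k]);
  }
  const double vdamp = std::exp(-damping_per_s * dt_s);

  NumericMatrix out_u(n_out, 3 * n_rec);   // receiver displacement, shell frame
  NumericVector out_t(n_out), out_ke(n_out);
  double R[3][3];

  int out_row = 0;
  for (int step = 0; step <= n_steps; ++step) {
    if (step > 0) {
      // advance shell anchors to the prescribed rigid rotation
      rot_matrix(axis, theta[step], R);
      for (int i = n_int; i < n_tot; ++i)
        for (int d = 0; d < 3; ++d)
          x[3 * i + d] = R[d][0] * X0(i, 0) + R[d][1] * X0(i, 1) + R[d][2] * X0(i, 2);

      std::fill(F.begin(), F.end(), 0.0);
      for (int e = 0; e < m; ++e) {
        const int i = springs(e, 0), j = springs(e, 1);
        double dx = x[3 * j] - x[3 * i];
        double dy = x[3 * j + 1] - x[3 * i + 1];
        double dz = x[3 * j + 2] - x[3 * i + 2];
        double L = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (L < 1e-9) continue;
        double eps = (L - rest_len[e]) / rest_len[e];
        double rad = std::sqrt(eps * eps + 4.0);
        double lam = 0.5 * (eps + rad);
        double la = std::pow(lam, alpha);
        double Te = mu[e] * (la - 1.0 / la) / rad;
        double sig = ghat_inf * Te;
        if (K > 0) {
          double dT = Te - Te_prev[e];
          for (int k = 0; k < K; ++k) {
            double &hk = h[e * K + k];
            hk = ek[k] * hk + ak[k] * dT;
            sig += hk;
          }
        }
        Te_prev[e] = Te;
        double f = coef[e] * sig / L;       // mN per mm of direction vector
        if (i < n_int) { F[3 * i] += f * dx; F[3 * i + 1] += f * dy; F[3 * i + 2] += f * dz; }
        if (j < n_int) { F[3 * j] -= f * dx; F[3 * j + 1] -= f * dy; F[3 * j + 2] -= f * dz; }
      }
      for (int i = 0; i < n_int; ++i)
        for (int d = 0; d < 3; ++d) {
          double &vi = v[3 * i + d];
          vi = vi * vdamp + dt_s * F[3 * i + d] / mass[i];   // mm/s
          x[3 * i + d] += dt_s * vi;
        }
    }

    if (step % out_every == 0) {
      rot_matrix(axis, theta[step], R);
      out_t[out_row] = step * dt_ms;
      double ke = 0.0;
      for (int i = 0; i < n_int; ++i)
        ke += 0.5 * mass[i] * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                               v[3 * i + 2] * v[3 * i + 2]) * 1e-6;   // J (mm/s -> m/s)
      out_ke[out_row] = ke;
      for (int r = 0; r < n_rec; ++r) {
        int i = receivers[r];
        double u[3];
        for (int d = 0; d < 3; ++d)       // back-rotate into the shell frame
          u[d] = R[0][d] * x[3 * i] + R[1][d] * x[3 * i + 1] + R[2][d] * x[3 * i + 2]
                 - X0(i, d);
        out_u(out_row, 3 * r) = u[0];
        out_u(out_row, 3 * r + 1) = u[1];
        out_u(out_row, 3 * r + 2) = u[2];
      }
      ++out_row;
    }

    if (step % 400 == 0) {
      for (int i = 0; i < n_int; ++i)
        for (int d = 0; d < 3; ++d)
          if (!std::isfinite(x[3 * i + d]) || std::fabs(x[3 * i + d]) > blowup_limit_mm)
            return List::create(_["ok"] = false, _["step"] = step);
    }
  }

  // final interior node displacements in the shell frame (for field export)
  rot_matrix(axis, theta[n_steps], R);
  NumericMatrix u_final(n_int, 3);
  for (int i = 0; i < n_int; ++i)
    for (int d = 0; d < 3; ++d)
      u_final(i, d) = R[0][d] * x[3 * i] + R[1][d] * x[3 * i + 1] +
                      R[2][d] * x[3 * i + 2] - X0(i, d);

  return List::create(_["ok"] = true, _["time_ms"] = out_t, _["u"] = out_u,
                      _["kinetic_j"] = out_ke, _["u_final"] = u_final);
}
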