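// Compiled kernels: 12-6-4 pair energies/forces, rational-switch coordination
// numbers with analytic gradients, and the BAOAB Langevin integrator.
// All quantities are in reduced units (energy k_BT, mass 1). Particle indices
// arriving from R are 1-based and converted here.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rational switching function s(x) = (1 - x^n)/(1 - x^m), x = d/r0, evaluated
// through the geometric-sum factorisation s(x) = (sum_{k<n} x^k)/(sum_{k<m} x^k),
// finite and smooth for all x >= 0; the removable singularity at x = 1
// evaluates to n/m exactly.
static inline void switch_eval(double x, int n, int m, double &s, double &dsdx) {
  double P = 1.0, Q = 1.0, dP = 0.0, dQ = 0.0, xk = 1.0, dxk = 0.0;
  for (int k = 1; k < m; ++k) {
    // xk = x^k, dxk = k x^{k-1}, updated incrementally
    dxk = dxk * x + xk;
    xk *= x;
    if (k < n) { P += xk; dP += dxk; }
    Q += xk; dQ += dxk;
  }
  s = P / Q;
  dsdx = (dP * Q - P * dQ) / (Q * Q);
}

// [[Rcpp::export]]
NumericMatrix cpp_switch(NumericVector d, double r0, int nexp, int mexp) {
  int n = d.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double s, dsdx;
    switch_eval(d[i] / r0, nexp, mexp, s, dsdx);
    out(i, 0) = s;
    out(i, 1) = dsdx / r0;  // ds/dd
  }
  return out;
}

// 12-6-4 pair energy and dU/dr (no cutoff handling; caller truncates)
static inline void pair_eval(double r, double c12, double c6, double c4,
                             double qq, double &u, double &dudr) {
  double inv = 1.0 / r, inv2 = inv * inv;
  double inv4 = inv2 * inv2, inv6 = inv4 * inv2, inv12 = inv6 * inv6;
  u = c12 * inv12 - c6 * inv6 - c4 * inv4 + qq * inv;
  dudr = (-12.0 * c12 * inv12 + 6.0 * c6 * inv6 + 4.0 * c4 * inv4 - qq * inv) * inv;
}

// Physical (unbiased) energy and forces. pairs: (i, j, c12, c6, c4, qq, cutoff);
// bonds: (i, j, k_bond, r_eq); tether: (i, k_tether, x0, y0, z0).
// Returns the smallest nonbonded pair distance seen via min_r.
static double phys_forces(const NumericMatrix &pos, const NumericMatrix &pairs,
                          const NumericMatrix &bonds, const NumericMatrix &tether,
                          NumericMatrix &F, double &min_r) {
  int N = pos.nrow();
  std::fill(F.begin(), F.end(), 0.0);
  double U = 0.0;
  min_r = R_PosInf;
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = (int)pairs(p, 0) - 1, j = (int)pairs(p, 1) - 1;
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < min_r) min_r = r;
    if (r >= pairs(p, 6) || r <= 0.0) continue;  // plain truncation at cutoff
    double u, dudr;
    pair_eval(r, pairs(p, 2), pairs(p, 3), pairs(p, 4), pairs(p, 5), u, dudr);
    U += u;
    double fac = -dudr / r;  // force on i along (ri - rj)
    F(i, 0) += fac * dx; F(i, 1) += fac * dy; F(i, 2) += fac * dz;
    F(j, 0) -= fac * dx; F(j, 1) -= fac * dy; F(j, 2) -= fac * dz;
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = (int)bonds(b, 0) - 1, j = (int)bonds(b, 1) - 1;
    double dx = pos(i, 0) - pos(j, 0);
    double dy = pos(i, 1) - pos(j, 1);
    double dz = pos(i, 2) - pos(j, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double kb = bonds(b, 2), req = bonds(b, 3);
    double dr = r - req;
    U += 0.5 * kb * dr * dr;
    if (r > 0) {
      double fac = -kb * dr / r;
      F(i, 0) += fac * dx; F(i, 1) += fac * dy; F(i, 2) += fac * dz;
      F(j, 0) -= fac * dx; F(j, 1) -= fac * dy; F(j, 2) -= fac * dz;
    }
  }
  for (int t = 0; t < tether.nrow(); ++t) {
    int i = (int)tether(t, 0) - 1;
    double kt = tether(t, 1);
    double dx = pos(i, 0) - tether(t, 2);
    double dy = pos(i, 1) - tether(t, 3);
    double dz = pos(i, 2) - tether(t, 4);
    U += 0.5 * kt * (dx * dx + dy * dy + dz * dz);
    F(i, 0) -= kt * dx; F(i, 1) -= kt * dy; F(i, 2) -= kt * dz;
  }
  (void)N;
  return U;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericMatrix pairs,
                       NumericMatrix bonds, NumericMatrix tether,
                       double rmin_guard) {
  NumericMatrix F(pos.nrow(), 3);
  double min_r;
  double U = phys_forces(pos, pairs, bonds, tether, F, min_r);
  bool ok = !(min_r < rmin_guard) && R_finite(U);
  return List::create(_["energy"] = U, _["forces"] = F,
                      _["min_pair_distance"] = min_r, _["ok"] = ok);
}

// Coordination number CN = sum_i s(d_i / r0) over members around a center,
// with the full analytic gradient matrix (N x 3).
static double cn_eval(const NumericMatrix &pos, int center,
                      const IntegerVector &members, double r0, int nexp,
                      int mexp, NumericMatrix *grad) {
  double cn = 0.0;
  for (int k = 0; k < members.size(); ++k) {
    int i = members[k] - 1;
    double dx = pos(center, 0) - pos(i, 0);
    double dy = pos(center, 1) - pos(i, 1);
    double dz = pos(center, 2) - pos(i, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    double s, dsdx;
    switch_eval(d / r0, nexp, mexp, s, dsdx);
    cn += s;
    if (grad != nullptr && d > 0) {
      double fac = (dsdx / r0) / d;  // d(s)/d(center coords) factor
      (*grad)(center, 0) += fac * dx;
      (*grad)(center, 1) += fac * dy;
      (*grad)(center, 2) += fac * dz;
      (*grad)(i, 0) -= fac * dx;
      (*grad)(i, 1) -= fac * dy;
      (*grad)(i, 2) -= fac * dz;
    }
  }
  return cn;
}

// [[Rcpp::export]]
List cpp_coordination(NumericMatrix pos, int center, IntegerVector members,
                      double r0, int nexp, int mexp) {
  NumericMatrix grad(pos.nrow(), 3);
  double cn = cn_eval(pos, center - 1, members, r0, nexp, mexp, &grad);
  return List::create(_["value"] = cn, _["gradient"] = grad);
}

// BAOAB Langevin integrator with an optional harmonic umbrella bias on the
// first collective variable. cvs is a list of lists with fields
// center, members, r0, nexp, mexp. Noise is drawn from R's RNG so that
// trajectories are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_run_baoab(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                   NumericMatrix pairs, NumericMatrix bonds,
                   NumericMatrix tether, List cvs, double bias_k,
                   double bias_center, double dt, double gamma,
                   double temperature, int n_steps, int save_stride,
                   bool save_frames, double rmin_guard, double energy_guard) {
  RNGScope scope;
  int N = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  NumericMatrix F(N, 3), cngrad(N, 3);
  int ncv = cvs.size();
  std::vector<int> cv_center(ncv);
  std::vector<IntegerVector> cv_members(ncv);
  std::vector<double> cv_r0(ncv);
  std::vector<int> cv_n(ncv), cv_m(ncv);
  for (int c = 0; c < ncv; ++c) {
    List cv = cvs[c];
    cv_center[c] = as<int>(cv["center"]) - 1;
    cv_members[c] = as<IntegerVector>(cv["members"]);
    cv_r0[c] = as<double>(cv["r0"]);
    cv_n[c] = as<int>(cv["nexp"]);
    cv_m[c] = as<int>(cv["mexp"]);
  }
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  int n_saved = n_steps / save_stride;
  NumericMatrix cv_out(n_saved, std::max(1, ncv));
  NumericVector epot(n_saved), ekin(n_saved), tvec(n_saved);
  NumericVector frames(save_frames ? (R_xlen_t)n_saved * N * 3 : (R_xlen_t)0);

  // Full force (physical + bias) at current positions; returns potential
  // energy including the bias term, records unbiased cv values.
  std::vector<double> cvvals(std::max(1, ncv), 0.0);
  double min_r;
  auto full_force = [&](double &u_phys, double &u_bias) -> bool {
    u_phys = phys_forces(pos, pairs, bonds, tether, F, min_r);
    u_bias = 0.0;
    if (min_r < rmin_guard || !R_finite(u_phys)) return false;
    for (int c = 0; c < ncv; ++c) {
      if (c == 0 && bias_k > 0) {
        std::fill(cngrad.begin(), cngrad.end(), 0.0);
        cvvals[c] = cn_eval(pos, cv_center[c], cv_members[c], cv_r0[c],
                            cv_n[c], cv_m[c], &cngrad);
        double dev = cvvals[c] - bias_center;
        u_bias = 0.5 * bias_k * dev * dev;
        for (int i = 0; i < N; ++i)
          for (int d = 0; d < 3; ++d) F(i, d) -= bias_k * dev * cngrad(i, d);
      } else {
        cvvals[c] = cn_eval(pos, cv_center[c], cv_members[c], cv_r0[c],
                            cv_n[c], cv_m[c], nullptr);
      }
    }
    return R_finite(u_phys + u_bias) && std::fabs(u_phys + u_bias) <= energy_guard;
  };

  double u_phys, u_bias;
  if (!full_force(u_phys, u_bias))
    return List::create(_["ok"] = false, _["error_step"] = 0,
                        _["min_pair_distance"] = min_r);

  int isave = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < N; ++i) {
      double hdtm = 0.5 * dt / mass[i];
      for (int d = 0; d < 3; ++d) {
        vel(i, d) += hdtm * F(i, d);                 // B
        pos(i, d) += 0.5 * dt * vel(i, d);           // A
      }
    }
    if (gamma > 0) {
      for (int i = 0; i < N; ++i) {
        double sig = c2 * std::sqrt(temperature / mass[i]);
        for (int d = 0; d < 3; ++d)
          vel(i, d) = c1 * vel(i, d) + sig * norm_rand();  // O
      }
    }
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) pos(i, d) += 0.5 * dt * vel(i, d);  // A
    if (!full_force(u_phys, u_bias))
      return List::create(_["ok"] = false, _["error_step"] = step,
                          _["min_pair_distance"] = min_r);
    for (int i = 0; i < N; ++i) {
      double hdtm = 0.5 * dt / mass[i];
      for (int d = 0; d < 3; ++d) vel(i, d) += hdtm * F(i, d);  // B
    }
    if (step % save_stride == 0) {
      double ke = 0.0;
      for (int i = 0; i < N; ++i)
        if (R_finite(mass[i]))  // infinite mass marks frozen particles
          ke += 0.5 * mass[i] * (vel(i, 0) * vel(i, 0) + vel(i, 1) * vel(i, 1) +
                                 vel(i, 2) * vel(i, 2));
      epot[isave] = u_phys + u_bias;
      ekin[isave] = ke;
      tvec[isave] = step * dt;
      for (int c = 0; c < ncv; ++c) cv_out(isave, c) = cvvals[c];
      if (save_frames) {
        R_xlen_t off = (R_xlen_t)isave * N * 3;
        for (int i = 0; i < N; ++i)
          for (int d = 0; d < 3; ++d) frames[off + i * 3 + d] = pos(i, d);
      }
      ++isave;
    }
  }
  List out = List::create(
      _["ok"] = true, _["cv"] = cv_out, _["epot"] = epot, _["ekin"] = ekin,
      _["time"] = tvec, _["final_pos"] = pos, _["final_vel"] = vel);
  if (save_frames) {
    frames.attr("dim") = IntegerVector::create(3, N, n_saved);
    out["frames"] = frames;
  }
  return out;
}
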