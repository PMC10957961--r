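// Pairwise particle kernels for the WCSPH solver.
//
// Conventions shared with the R layer:
//  * positions/velocities are n x d matrices (d = 1, 2 or 3);
//  * pair lists hold 1-based indices (i, j) with i < j, dx = x_i - x_j
//    (minimum image on periodic axes) and r = |dx|;
//  * tensors (velocity gradient, deformation gradient, PK1 stress) are
//    flattened row-major per particle into n x (d*d) matrices:
//    T[a, b] -> column a*d + b.
//  * tags: 0 fluid, 1 boundary-like (wall / rigid / flexible), 2 buffer.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline double alpha_d_of(int dim, double h) {
  if (dim == 1) return 3.0 / (4.0 * h);
  if (dim == 2) return 7.0 / (4.0 * M_PI * h * h);
  return 21.0 / (16.0 * M_PI * h * h * h);
}

// Wendland C2: W = alpha_d (1 - q/2)^4 (2q + 1), 0 <= q <= 2
static inline double wend_w(double q) {
  if (q >= 2.0) return 0.0;
  double t = 1.0 - 0.5 * q;
  double t2 = t * t;
  return t2 * t2 * (2.0 * q + 1.0);
}

// dW/dq = -5 q (1 - q/2)^3
static inline double wend_dwdq(double q) {
  if (q >= 2.0) return 0.0;
  double t = 1.0 - 0.5 * q;
  return -5.0 * q * t * t * t;
}

// [[Rcpp::export]]
List cpp_cell_pairs(NumericMatrix pos, double rcut,
                    NumericVector lo, NumericVector hi,
                    LogicalVector periodic) {
  const int n = pos.nrow();
  const int d = pos.ncol();
  const double rcut2 = rcut * rcut;

  for (int i = 0; i < n; ++i)
    for (int a = 0; a < d; ++a)
      if (!R_finite(pos(i, a)))
        stop("non-finite particle position (particle %d)", i + 1);

  int nc[3] = {1, 1, 1};
  double csz[3] = {rcut, rcut, rcut};
  double span[3];
  bool allpairs = (n <= 64);
  for (int a = 0; a < d; ++a) {
    span[a] = hi[a] - lo[a];
    if (periodic[a]) {
      nc[a] = std::max(1, (int)std::floor(span[a] / rcut));
      csz[a] = span[a] / nc[a];
      if (nc[a] < 3) allpairs = true;  // stencil would self-overlap
    } else {
      nc[a] = std::max(1, (int)std::floor(span[a] / rcut) + 1);
      csz[a] = rcut;
    }
  }

  std::vector<int> I, J;
  std::vector<double> DX, R;
  I.reserve(16 * n); J.reserve(16 * n);
  DX.reserve(16 * n * d); R.reserve(16 * n);

  auto min_image = [&](double* dx) {
    for (int a = 0; a < d; ++a) {
      if (periodic[a]) {
        if (dx[a] > 0.5 * span[a]) dx[a] -= span[a];
        else if (dx[a] < -0.5 * span[a]) dx[a] += span[a];
      }
    }
  };

  auto try_pair = [&](int i, int j) {
    double dx[3] = {0, 0, 0};
    for (int a = 0; a < d; ++a) dx[a] = pos(i, a) - pos(j, a);
    min_image(dx);
    double r2 = 0;
    for (int a = 0; a < d; ++a) r2 += dx[a] * dx[a];
    if (r2 < rcut2 && r2 > 0) {
      I.push_back(i + 1); J.push_back(j + 1);
      for (int a = 0; a < d; ++a) DX.push_back(dx[a]);
      R.push_back(std::sqrt(r2));
    }
  };

  if (allpairs) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) try_pair(i, j);
  } else {
    const int ncx = nc[0], ncy = (d > 1) ? nc[1] : 1, ncz = (d > 2) ? nc[2] : 1;
    const int ncells = ncx * ncy * ncz;
    std::vector<std::vector<int>> cells(ncells);
    std::vector<int> ci(n);
    for (int i = 0; i < n; ++i) {
      int idx[3] = {0, 0, 0};
      for (int a = 0; a < d; ++a) {
        int k = (int)std::floor((pos(i, a) - lo[a]) / csz[a]);
        if (periodic[a]) { k %= nc[a]; if (k < 0) k += nc[a]; }
        else { if (k < 0) k = 0; if (k >= nc[a]) k = nc[a] - 1; }
        idx[a] = k;
      }
      ci[i] = idx[0] + ncx * (idx[1] + ncy * idx[2]);
      cells[ci[i]].push_back(i);  // ascending i within each cell
    }
    std::vector<int> js;
    for (int i = 0; i < n; ++i) {
      int cx = ci[i] % ncx, cy = (ci[i] / ncx) % ncy, cz = ci[i] / (ncx * ncy);
      js.clear();
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = (d > 1 ? -1 : 0); oy <= (d > 1 ? 1 : 0); ++oy)
          for (int oz = (d > 2 ? -1 : 0); oz <= (d > 2 ? 1 : 0); ++oz) {
            int kx = cx + ox, ky = cy + oy, kz = cz + oz;
            if (periodic[0]) { kx = (kx + ncx) % ncx; }
            else if (kx < 0 || kx >= ncx) continue;
            if (d > 1) {
              if (periodic[1]) { ky = (ky + ncy) % ncy; }
              else if (ky < 0 || ky >= ncy) continue;
            }
            if (d > 2) {
              if (periodic[2]) { kz = (kz + ncz) % ncz; }
              else if (kz < 0 || kz >= ncz) continue;
            }
            const std::vector<int>& cell = cells[kx + ncx * (ky + ncy * kz)];
            for (int j : cell) if (j > i) js.push_back(j);
          }
      std::sort(js.begin(), js.end());
      js.erase(std::unique(js.begin(), js.end()), js.end());
      for (int j : js) try_pair(i, j);
    }
  }

  const int m = (int)I.size();
  IntegerVector Iv(m), Jv(m);
  NumericMatrix dxm(m, d);
  NumericVector rv(m);
  for (int k = 0; k < m; ++k) {
    Iv[k] = I[k]; Jv[k] = J[k]; rv[k] = R[k];
    for (int a = 0; a < d; ++a) dxm(k, a) = DX[k * d + a];
  }
  return List::create(_["i"] = Iv, _["j"] = Jv, _["dx"] = dxm, _["r"] = rv);
}

// Continuity (DBC-aware), momentum (pressure + Morris laminar viscosity +
// SPS sub-particle stresses) in one call.  Returns drho, acc and the raw
// velocity gradient used for the SPS closure.
// [[Rcpp::export]]
List cpp_fluid_rates(NumericMatrix pos, NumericMatrix vel,
                     NumericVector rho, NumericVector p,
                     NumericVector mass, IntegerVector tag,
                     IntegerVector pi, IntegerVector pj,
                     NumericMatrix dx, NumericVector r,
                     double h, int dim, double mu,
                     bool sps_on, double Cs, double CI, double ksps,
                     double dl, double delta_sph, double c0) {
  const int n = pos.nrow();
  const int d = dim;
  const int m = pi.size();
  const double ad = alpha_d_of(d, h);
  const double eps_h2 = 0.01 * h * h;

  NumericVector drho(n);
  NumericMatrix acc(n, d);
  NumericMatrix gradu(n, d * d);   // fluid-only velocity gradient
  std::vector<double> gw(m * d);   // cache grad W per pair

  // pass 1: kernel gradients + continuity + velocity gradient
  for (int k = 0; k < m; ++k) {
    const int i = pi[k] - 1, j = pj[k] - 1;
    const double q = r[k] / h;
    const double coef = ad * wend_dwdq(q) / (h * r[k]);  // gradW = coef * dx
    double dot = 0.0;
    double dv[3];
    for (int a = 0; a < d; ++a) {
      const double g = coef * dx(k, a);
      gw[k * d + a] = g;
      dv[a] = vel(i, a) - vel(j, a);
      dot += dv[a] * g;
    }
    // continuity: fluid sees everyone; boundary (DBC) sees fluid/buffer only;
    // buffer densities are prescribed by extrapolation, never integrated
    if (tag[i] == 0 || (tag[i] == 1 && tag[j] != 1))
      drho[i] += rho[i] * mass[j] / rho[j] * dot;
    if (tag[j] == 0 || (tag[j] == 1 && tag[i] != 1))
      drho[j] += rho[j] * mass[i] / rho[i] * dot;
    // optional delta-SPH density diffusion (fluid-fluid pairs only)
    if (delta_sph > 0.0 && tag[i] == 0 && tag[j] == 0) {
      double r2 = r[k] * r[k];
      double dgw = 0.0;
      for (int a = 0; a < d; ++a) dgw += dx(k, a) * gw[k * d + a];
      const double psi = 2.0 * (rho[j] - rho[i]) * (-dgw) / (r2 + eps_h2);
      const double dcoef = delta_sph * h * c0;
      drho[i] += dcoef * psi * mass[j] / rho[j];
      drho[j] -= dcoef * psi * mass[i] / rho[i];  // diffusion: antisymmetric
    }
    if (sps_on) {
      // raw SPH gradient: G_i[a,b] += V_j (u_j - u_i)_a gradW_b (note sign)
      const double Vj = mass[j] / rho[j], Vi = mass[i] / rho[i];
      for (int a = 0; a < d; ++a)
        for (int b = 0; b < d; ++b) {
          gradu(i, a * d + b) += Vj * (-dv[a]) * gw[k * d + b];
          gradu(j, a * d + b) += Vi * dv[a] * (-gw[k * d + b]);
        }
    }
  }

  // SPS stress tensor per particle (fluid only)
  NumericMatrix tau(n, d * d);
  if (sps_on) {
    for (int i = 0; i < n; ++i) {
      if (tag[i] != 0) continue;
      double S[9], ss = 0.0;
      for (int a = 0; a < d; ++a)
        for (int b = 0; b < d; ++b) {
          S[a * d + b] = 0.5 * (gradu(i, a * d + b) + gradu(i, b * d + a));
          ss += S[a * d + b] * S[a * d + b];
        }
      const double norm2 = 2.0 * ss;                 // 2 S:S
      const double muT = rho[i] * (Cs * dl) * (Cs * dl) * std::sqrt(norm2);
      const double iso = (2.0 / 3.0) * rho[i] * ksps +
                         (2.0 / 3.0) * CI * rho[i] * dl * dl * norm2;
      for (int a = 0; a < d; ++a)
        for (int b = 0; b < d; ++b) {
          tau(i, a * d + b) = 2.0 * muT * S[a * d + b] - (a == b ? iso : 0.0);
        }
    }
  }

  // pass 2: pairwise forces (skip boundary-boundary and buffer-boundary)
  for (int k = 0; k < m; ++k) {
    const int i = pi[k] - 1, j = pj[k] - 1;
    if (tag[i] != 0 && tag[j] != 0) continue;  // need one fluid side
    const double pr = -(p[i] + p[j]) / (rho[i] * rho[j]);
    const double mm = mass[i] * mass[j];
    const double r2 = r[k] * r[k];
    double dot_xg = 0.0;
    for (int a = 0; a < d; ++a) dot_xg += dx(k, a) * gw[k * d + a];
    const double visc = 2.0 * mu / (rho[i] * rho[j]) * dot_xg / (r2 + eps_h2);
    double F[3];
    for (int a = 0; a < d; ++a) {
      F[a] = mm * (pr * gw[k * d + a] + visc * (vel(i, a) - vel(j, a)));
    }
    if (sps_on) {
      for (int a = 0; a < d; ++a) {
        double s = 0.0;
        for (int b = 0; b < d; ++b)
          s += (tau(i, a * d + b) / (rho[i] * rho[i]) +
                tau(j, a * d + b) / (rho[j] * rho[j])) * gw[k * d + b];
        F[a] += mm * s;
      }
    }
    for (int a = 0; a < d; ++a) {
      acc(i, a) += F[a] / mass[i];
      acc(j, a) -= F[a] / mass[j];
    }
  }

  return List::create(_["drho"] = drho, _["acc"] = acc,
                      _["gradu"] = gradu, _["tau"] = tau);
}

// Continuity-only pass (same DBC gating and optional delta-SPH as
// cpp_fluid_rates) against a frozen pair geometry: used by the
// semi-implicit integrator, which integrates densities with the
// end-of-step velocities to keep the acoustic u-rho coupling stable.
// [[Rcpp::export]]
NumericVector cpp_continuity(NumericMatrix vel,
                             NumericVector rho, NumericVector mass,
                             IntegerVector tag,
                             IntegerVector pi, IntegerVector pj,
                             NumericMatrix dx, NumericVector r,
                             double h, int dim,
                             double delta_sph, double c0) {
  const int n = vel.nrow();
  const int d = dim;
  const int m = pi.size();
  const double ad = alpha_d_of(d, h);
  const double eps_h2 = 0.01 * h * h;
  NumericVector drho(n);
  for (int k = 0; k < m; ++k) {
    const int i = pi[k] - 1, j = pj[k] - 1;
    const double q = r[k] / h;
    const double coef = ad * wend_dwdq(q) / (h * r[k]);
    double dot = 0.0, dgw = 0.0;
    for (int a = 0; a < d; ++a) {
      const double g = coef * dx(k, a);
      dot += (vel(i, a) - vel(j, a)) * g;
      dgw += dx(k, a) * g;
    }
    if (tag[i] == 0 || (tag[i] == 1 && tag[j] != 1))
      drho[i] += rho[i] * mass[j] / rho[j] * dot;
    if (tag[j] == 0 || (tag[j] == 1 && tag[i] != 1))
      drho[j] += rho[j] * mass[i] / rho[i] * dot;
    if (delta_sph > 0.0 && tag[i] == 0 && tag[j] == 0) {
      const double r2 = r[k] * r[k];
      const double psi = 2.0 * (rho[j] - rho[i]) * (-dgw) / (r2 + eps_h2);
      const double dcoef = delta_sph * h * c0;
      drho[i] += dcoef * psi * mass[j] / rho[j];
      drho[j] -= dcoef * psi * mass[i] / rho[i];
    }
  }
  return drho;
}

// small dense solve (Gauss, partial pivot); A is k x k row-major, b k x nrhs
static bool solve_small(double* A, double* b, int k, int nrhs) {
  for (int c = 0; c < k; ++c) {
    int piv = c;
    for (int rr = c + 1; rr < k; ++rr)
      if (std::fabs(A[rr * k + c]) > std::fabs(A[piv * k + c])) piv = rr;
    if (std::fabs(A[piv * k + c]) < 1e-14) return false;
    if (piv != c) {
      for (int cc = 0; cc < k; ++cc) std::swap(A[c * k + cc], A[piv * k + cc]);
      for (int cc = 0; cc < nrhs; ++cc) std::swap(b[c * nrhs + cc], b[piv * nrhs + cc]);
    }
    const double inv = 1.0 / A[c * k + c];
    for (int rr = 0; rr < k; ++rr) {
      if (rr == c) continue;
      const double f = A[rr * k + c] * inv;
      if (f == 0.0) continue;
      for (int cc = c; cc < k; ++cc) A[rr * k + cc] -= f * A[c * k + cc];
      for (int cc = 0; cc < nrhs; ++cc) b[rr * nrhs + cc] -= f * b[c * nrhs + cc];
    }
  }
  for (int c = 0; c < k; ++c) {
    const double inv = 1.0 / A[c * k + c];
    for (int cc = 0; cc < nrhs; ++cc) b[c * nrhs + cc] *= inv;
  }
  return true;
}

// First-order consistent (corrected) velocity gradient at selected particles.
// eval: logical per particle; use: logical per particle (neighbour data used).
// Returns G (n x d*d, rows only valid where eval) and ok flag per particle.
// [[Rcpp::export]]
List cpp_corrected_gradient(NumericMatrix pos, NumericMatrix vel,
                            NumericVector vol,
                            LogicalVector eval, LogicalVector use,
                            IntegerVector pi, IntegerVector pj,
                            NumericMatrix dx, NumericVector r,
                            double h, int dim) {
  const int n = pos.nrow();
  const int d = dim;
  const int m = pi.size();
  const double ad = alpha_d_of(d, h);

  std::vector<double> A(n * d * d, 0.0), M(n * d * d, 0.0);

  auto accum = [&](int i, int j, const double* dxv, double rr) {
    // contribution of neighbour j to evaluation point i; dxv = x_i - x_j
    const double q = rr / h;
    const double coef = ad * wend_dwdq(q) / (h * rr);
    for (int a = 0; a < d; ++a) {
      const double xa = -dxv[a];               // (x_j - x_i)_a
      const double va = vel(j, a) - vel(i, a);
      for (int b = 0; b < d; ++b) {
        const double g = coef * dxv[b];        // (grad_i W)_b
        A[(i * d + a) * d + b] += vol[j] * va * g;
        M[(i * d + a) * d + b] += vol[j] * xa * g;
      }
    }
  };

  for (int k = 0; k < m; ++k) {
    const int i = pi[k] - 1, j = pj[k] - 1;
    double dxv[3];
    for (int a = 0; a < d; ++a) dxv[a] = dx(k, a);
    if (eval[i] && use[j]) accum(i, j, dxv, r[k]);
    if (eval[j] && use[i]) {
      double neg[3];
      for (int a = 0; a < d; ++a) neg[a] = -dxv[a];
      accum(j, i, neg, r[k]);
    }
  }

  NumericMatrix G(n, d * d);
  LogicalVector ok(n);
  double Mi[9], rhs[9];
  for (int i = 0; i < n; ++i) {
    if (!eval[i]) { ok[i] = false; continue; }
    // solve G = A * M^{-1}  <=>  M^T G^T = A^T
    for (int a = 0; a < d; ++a)
      for (int b = 0; b < d; ++b) {
        Mi[a * d + b] = M[(i * d + b) * d + a];      // M^T
        rhs[a * d + b] = A[(i * d + b) * d + a];     // A^T (cols of G^T)
      }
    bool good = solve_small(Mi, rhs, d, d);
    ok[i] = good;
    if (good)
      for (int a = 0; a < d; ++a)
        for (int b = 0; b < d; ++b)
          G(i, a * d + b) = rhs[b * d + a];
  }
  return List::create(_["G"] = G, _["ok"] = ok);
}

// Moving-least-squares (linear basis) field evaluation at query points from
// scattered source particles.  vals: ns x k fields.  Returns fitted value and
// gradient of each field at each query point; ok = linear fit succeeded.
// [[Rcpp::export]]
List cpp_mls_eval(NumericMatrix query, NumericMatrix src,
                  NumericMatrix vals, NumericVector vol,
                  double h, int dim) {
  const int nq = query.nrow(), ns = src.nrow(), nf = vals.ncol();
  const int d = dim, k = d + 1;
  const double ad = alpha_d_of(d, h);
  const double rcut2 = 4.0 * h * h;

  NumericMatrix out(nq, nf), grad(nq, nf * d);
  LogicalVector ok(nq);

  std::vector<double> Amat(k * k), rhs(k * nf);
  for (int qi = 0; qi < nq; ++qi) {
    std::fill(Amat.begin(), Amat.end(), 0.0);
    std::fill(rhs.begin(), rhs.end(), 0.0);
    double wsum = 0.0;
    std::vector<double> shep(nf, 0.0);
    for (int s = 0; s < ns; ++s) {
      double dxv[3], r2 = 0.0;
      for (int a = 0; a < d; ++a) {
        dxv[a] = src(s, a) - query(qi, a);
        r2 += dxv[a] * dxv[a];
      }
      if (r2 >= rcut2) continue;
      const double w = ad * wend_w(std::sqrt(r2) / h) * vol[s];
      double basis[4] = {1.0, 0.0, 0.0, 0.0};
      for (int a = 0; a < d; ++a) basis[a + 1] = dxv[a];
      for (int a = 0; a < k; ++a)
        for (int b = 0; b < k; ++b)
          Amat[a * k + b] += w * basis[a] * basis[b];
      for (int f = 0; f < nf; ++f)
        for (int a = 0; a < k; ++a)
          rhs[a * nf + f] += w * basis[a] * vals(s, f);
      wsum += w;
      for (int f = 0; f < nf; ++f) shep[f] += w * vals(s, f);
    }
    std::vector<double> Acopy(Amat), rcopy(rhs);
    bool good = wsum > 1e-12 && solve_small(Acopy.data(), rcopy.data(), k, nf);
    ok[qi] = good;
    if (good) {
      for (int f = 0; f < nf; ++f) {
        out(qi, f) = rcopy[0 * nf + f];
        for (int a = 0; a < d; ++a) grad(qi, f * d + a) = rcopy[(a + 1) * nf + f];
      }
    } else if (wsum > 1e-12) {  // Shepard fallback, zero gradient
      for (int f = 0; f < nf; ++f) out(qi, f) = shep[f] / wsum;
    } else {
      for (int f = 0; f < nf; ++f) out(qi, f) = NA_REAL;
    }
  }
  return List::create(_["val"] = out, _["grad"] = grad, _["ok"] = ok);
}

// Reference-configuration kernel-gradient correction matrices (total
// Lagrangian).  Returns Minv with convention  F = A * Minv  where
// A = sum_j V0_j (x_j - x_i) (x) grad0 W_ij.
// [[Rcpp::export]]
List cpp_ref_correction(NumericMatrix X, NumericVector V0,
                        IntegerVector pi, IntegerVector pj,
                        NumericMatrix dx, NumericVector r,
                        double h, int dim) {
  const int n = X.nrow(), d = dim, m = pi.size();
  const double ad = alpha_d_of(d, h);
  std::vector<double> M(n * d * d, 0.0);

  for (int k = 0; k < m; ++k) {
    const int i = pi[k] - 1, j = pj[k] - 1;
    const double q = r[k] / h;
    const double coef = ad * wend_dwdq(q) / (h * r[k]);
    for (int a = 0; a < d; ++a) {
      const double xa = -dx(k, a);  // (X_j - X_i)_a
      for (int b = 0; b < d; ++b) {
        const double g = coef * dx(k, b);  // (grad0_i W)_b
        M[(i * d + a) * d + b] += V0[j] * xa * g;
        M[(j * d + a) * d + b] += V0[i] * xa * g;  // both signs flip: same
      }
    }
  }

  NumericMatrix Minv(n, d * d);
  LogicalVector ok(n);
  double Mi[9], Id[9];
  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < d; ++a)
      for (int b = 0; b < d; ++b) {
        Mi[a * d + b] = M[(i * d + a) * d + b];
        Id[a * d + b] = (a == b) ? 1.0 : 0.0;
      }
    ok[i] = solve_small(Mi, Id, d, d);  // Id <- M^{-1}
    if (ok[i])
      for (int a = 0; a < d; ++a)
        for (int b = 0; b < d; ++b)
          Minv(i, a * d + b) = Id[a * d + b];
  }
  return List::create(_["Minv"] = Minv, _["ok"] = ok);
}

// Deformation gradient F_i = [sum_j V0_j (x_j - x_i)(x)grad0 W_ij] * Minv_i
// [[Rcpp::export]]
NumericMatrix cpp_deformation_gradient(NumericMatrix xcur, NumericVector V0,
                                       NumericMatrix Minv,
                                       IntegerVector pi, IntegerVector pj,
                                       NumericMatrix dx, NumericVector r,
                                       double h, int dim) {
  const int n = xcur.nrow(), d = dim, m = pi.size();
  const double ad = alpha_d_of(d, h);
  std::vector<double> A(n * d * d, 0.0);

  for (int k = 0; k < m; ++k) {
    const int i = pi[k] - 1, j = pj[k] - 1;
    const double q = r[k] / h;
    const double coef = ad * wend_dwdq(q) / (h * r[k]);
    for (int a = 0; a < d; ++a) {
      const double xa = xcur(j, a) - xcur(i, a);
      for (int b = 0; b < d; ++b) {
        const double g = coef * dx(k, b);
        A[(i * d + a) * d + b] += V0[j] * (-xa) * (-g);   // (x_j-x_i)(grad_i W)
        A[(j * d + a) * d + b] += V0[i] * (-xa) * (-g);   // sym: both flip
      }
    }
  }

  NumericMatrix F(n, d * d);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < d; ++a)
      for (int b = 0; b < d; ++b) {
        double s = 0.0;
        for (int c = 0; c < d; ++c)
          s += A[(i * d + a) * d + c] * Minv(i, c * d + b);
        F(i, a * d + b) = s;
      }
  return F;
}

// Total-Lagrangian internal accelerations:
//   a_i = (1/m_i) sum_j V0_i V0_j (P_i B_i + P_j B_j) grad0 W_ij
// with B = Minv^T, plus Monaghan artificial viscosity evaluated on the
// current configuration but paired over the reference adjacency.
// [[Rcpp::export]]
NumericMatrix cpp_solid_accel(NumericMatrix xcur, NumericMatrix vel,
                              NumericVector V0, NumericVector mass,
                              NumericMatrix P, NumericMatrix Minv,
                              IntegerVector pi, IntegerVector pj,
                              NumericMatrix dx, NumericVector r,
                              double h, int dim,
                              double alpha_visc, double c0s, double rho0s) {
  const int n = xcur.nrow(), d = dim, m = pi.size();
  const double ad = alpha_d_of(d, h);
  const double eps_h2 = 0.01 * h * h;
  NumericMatrix acc(n, d);

  for (int k = 0; k < m; ++k) {
    const int i = pi[k] - 1, j = pj[k] - 1;
    const double q = r[k] / h;
    const double coef = ad * wend_dwdq(q) / (h * r[k]);
    double g0[3];
    for (int a = 0; a < d; ++a) g0[a] = coef * dx(k, a);  // grad0_i W_ij

    double F[3] = {0, 0, 0};
    for (int a = 0; a < d; ++a) {
      double s = 0.0;
      for (int b = 0; b < d; ++b) {
        double PBi = 0.0, PBj = 0.0;
        for (int c = 0; c < d; ++c) {
          // B = Minv^T: B[c,b] = Minv[b,c]
          PBi += P(i, a * d + c) * Minv(i, b * d + c);
          PBj += P(j, a * d + c) * Minv(j, b * d + c);
        }
        s += (PBi + PBj) * g0[b];
      }
      F[a] = V0[i] * V0[j] * s;
    }

    if (alpha_visc > 0.0) {
      double xc[3], vv[3], dot = 0.0, r2 = 0.0;
      for (int a = 0; a < d; ++a) {
        xc[a] = xcur(i, a) - xcur(j, a);
        vv[a] = vel(i, a) - vel(j, a);
        dot += xc[a] * vv[a];
        r2 += xc[a] * xc[a];
      }
      if (dot < 0.0) {
        const double muv = h * dot / (r2 + eps_h2);
        const double piv = -alpha_visc * c0s * muv / rho0s;
        for (int a = 0; a < d; ++a)
          F[a] -= mass[i] * mass[j] * piv * g0[a];
      }
    }

    for (int a = 0; a < d; ++a) {
      acc(i, a) += F[a] / mass[i];
      acc(j, a) -= F[a] / mass[j];
    }
  }
  return acc;
}
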