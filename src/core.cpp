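// Compiled kernels: neighbour search, MMLS shape functions, total-Lagrangian
// Neo-Hookean force assembly, damped central-difference relaxation, and
// voxel occupancy classification. All heavy per-step loops live here; the R
// layer owns orchestration, units and validation.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <complex>
#include <cmath>
#if defined(__SSE2__)
#include <xmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef std::complex<double> cplx;

// ---------------------------------------------------------------------------
// Cell-list radius search. Returns CSR neighbour lists (0-based indices).
// Per-query radii allow local support enlargement without a rebuild.
// ---------------------------------------------------------------------------
static inline long long cell_key(int ix, int iy, int iz) {
  // offset to keep keys positive-ish; grids here are far below 2^20 cells
  const long long B = 1 << 20;
  return ((long long)(ix + 524288)) + B * ((long long)(iy + 524288)) +
         B * B * ((long long)(iz + 524288));
}

// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix pts, NumericMatrix query,
                          NumericVector radius) {
  const int n = pts.nrow(), m = query.nrow();
  double rmax = 0.0;
  for (int i = 0; i < m; ++i) rmax = std::max(rmax, radius[i]);
  if (rmax <= 0.0) stop("search radius must be positive");
  const double cell = rmax;
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(pts(i, 0) / cell);
    int iy = (int)std::floor(pts(i, 1) / cell);
    int iz = (int)std::floor(pts(i, 2) / cell);
    grid[cell_key(ix, iy, iz)].push_back(i);
  }
  std::vector<int> ptr(m + 1, 0);
  std::vector<int> idx;
  idx.reserve((size_t)m * 32);
  for (int q = 0; q < m; ++q) {
    const double r = radius[q], r2 = r * r;
    const double x = query(q, 0), y = query(q, 1), z = query(q, 2);
    int ix = (int)std::floor(x / cell), iy = (int)std::floor(y / cell),
        iz = (int)std::floor(z / cell);
    int span = (int)std::ceil(r / cell);
    for (int a = ix - span; a <= ix + span; ++a)
      for (int b = iy - span; b <= iy + span; ++b)
        for (int c = iz - span; c <= iz + span; ++c) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
              grid.find(cell_key(a, b, c));
          if (it == grid.end()) continue;
          const std::vector<int>& bucket = it->second;
          for (size_t t = 0; t < bucket.size(); ++t) {
            int j = bucket[t];
            double dx = pts(j, 0) - x, dy = pts(j, 1) - y, dz = pts(j, 2) - z;
            if (dx * dx + dy * dy + dz * dz <= r2) idx.push_back(j);
          }
        }
    ptr[q + 1] = (int)idx.size();
  }
  return List::create(_["ptr"] = wrap(ptr), _["idx"] = wrap(idx));
}

// ---------------------------------------------------------------------------
// MMLS shape functions.
//
// Quadratic basis p(xi) = [1, xi, eta, zeta, xi^2, eta^2, zeta^2,
//                          xi*eta, eta*zeta, zeta*xi], xi = (X_j - x)/h.
// Regularised-singular weight w(r) = 1/((r/h)^2 + eps_w) over the support
// set (truncation is realised by support selection), giving near-delta
// interpolation at nodes. Diagonal penalty mu_p = pen_factor * tr(A)/10 on
// the six quadratic coefficients keeps the moment matrix invertible when
// only linear reproduction is supported.
//
// Gradients are exact derivatives of this evaluation (including the
// trace-dependent penalty), obtained by complex-step differentiation.
// ---------------------------------------------------------------------------
static void mmls_eval_point(const NumericMatrix& nodes, const int* sup, int k,
                            const cplx x[3], double h, double pen_factor,
                            double eps_w, std::vector<cplx>& phi_out,
                            double* rcond_out) {
  arma::cx_mat A(10, 10, arma::fill::zeros);
  std::vector<cplx> w(k);
  std::vector<cplx> P((size_t)k * 10);
  for (int j = 0; j < k; ++j) {
    int nj = sup[j];
    cplx d0 = (nodes(nj, 0) - x[0]) / h;
    cplx d1 = (nodes(nj, 1) - x[1]) / h;
    cplx d2 = (nodes(nj, 2) - x[2]) / h;
    cplx* p = &P[(size_t)j * 10];
    p[0] = 1.0; p[1] = d0; p[2] = d1; p[3] = d2;
    p[4] = d0 * d0; p[5] = d1 * d1; p[6] = d2 * d2;
    p[7] = d0 * d1; p[8] = d1 * d2; p[9] = d2 * d0;
    cplx r2 = d0 * d0 + d1 * d1 + d2 * d2;
    w[j] = 1.0 / (r2 + eps_w);
    for (int a = 0; a < 10; ++a)
      for (int b = a; b < 10; ++b) A(a, b) += w[j] * p[a] * p[b];
  }
  for (int a = 0; a < 10; ++a)
    for (int b = 0; b < a; ++b) A(a, b) = A(b, a);
  cplx tr(0.0, 0.0);
  for (int a = 0; a < 10; ++a) tr += A(a, a);
  cplx mu_p = pen_factor * tr / 10.0;
  for (int a = 4; a < 10; ++a) A(a, a) += mu_p;
  if (rcond_out) {
    arma::mat Ar = arma::real(A);
    *rcond_out = arma::rcond(Ar);
  }
  arma::cx_vec rhs(10, arma::fill::zeros);
  rhs(0) = 1.0;
  arma::cx_vec gamma = arma::solve(A, rhs, arma::solve_opts::fast);
  phi_out.resize(k);
  for (int j = 0; j < k; ++j) {
    const cplx* p = &P[(size_t)j * 10];
    cplx acc(0.0, 0.0);
    for (int a = 0; a < 10; ++a) acc += p[a] * gamma(a);
    phi_out[j] = w[j] * acc;
  }
}

// [[Rcpp::export]]
List cpp_mmls_batch(NumericMatrix nodes, NumericMatrix evalpts,
                    IntegerVector ptr, IntegerVector idx0, NumericVector hvec,
                    double pen_factor, double eps_w, bool want_grad) {
  const int m = evalpts.nrow();
  const int nnz = idx0.size();
  NumericVector phi(nnz), gx(want_grad ? nnz : 0), gy(want_grad ? nnz : 0),
      gz(want_grad ? nnz : 0);
  double rcond_min = 1.0;
  int worst_eval = 0;
  const double delta = 1e-30;  // complex-step size, mm
  std::vector<cplx> ph;
  for (int e = 0; e < m; ++e) {
    int lo = ptr[e], hi = ptr[e + 1], k = hi - lo;
    if (k < 1) stop("empty support at evaluation point %d", e + 1);
    const int* sup = idx0.begin() + lo;
    double h = hvec[e];
    cplx x[3] = {cplx(evalpts(e, 0), 0.0), cplx(evalpts(e, 1), 0.0),
                 cplx(evalpts(e, 2), 0.0)};
    double rc = 1.0;
    mmls_eval_point(nodes, sup, k, x, h, pen_factor, eps_w, ph, &rc);
    if (rc < rcond_min) { rcond_min = rc; worst_eval = e + 1; }
    for (int j = 0; j < k; ++j) phi[lo + j] = ph[j].real();
    if (want_grad) {
      for (int d = 0; d < 3; ++d) {
        cplx xc[3] = {x[0], x[1], x[2]};
        xc[d] += cplx(0.0, delta);
        mmls_eval_point(nodes, sup, k, xc, h, pen_factor, eps_w, ph, NULL);
        NumericVector& g = (d == 0) ? gx : ((d == 1) ? gy : gz);
        for (int j = 0; j < k; ++j) g[lo + j] = ph[j].imag() / delta;
      }
    }
  }
  return List::create(_["phi"] = phi, _["gx"] = gx, _["gy"] = gy,
                      _["gz"] = gz, _["rcond_min"] = rcond_min,
                      _["worst_eval"] = worst_eval);
}

// ---------------------------------------------------------------------------
// Total-Lagrangian internal forces for the decoupled near-incompressible
// Neo-Hookean model. Units: stresses kPa, lengths mm, forces mN (kPa*mm^2),
// energies microjoule (kPa*mm^3).
//   F = I + sum_a u_a (x) grad0 phi_a
//   W = mu/2 (J^{-2/3} I1 - 3) + kappa/2 (J-1)^2
//   P = mu J^{-2/3} (F - I1/3 F^{-T}) + kappa (J-1) J F^{-T}
// ---------------------------------------------------------------------------
static inline bool ip_force3(const double* u3, const int* idx,
                             const double* gx, const double* gy,
                             const double* gz, int lo, int hi, double wq,
                             double mu, double kappa, double* f3,
                             double* Wout, double* Jout,
                             double jclamp = 0.0) {
  double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};  // row-major F[3r+c]
  for (int t = lo; t < hi; ++t) {
    const double* ua = u3 + 3 * idx[t];
    double g0 = gx[t], g1 = gy[t], g2 = gz[t];
    F[0] += ua[0] * g0; F[1] += ua[0] * g1; F[2] += ua[0] * g2;
    F[3] += ua[1] * g0; F[4] += ua[1] * g1; F[5] += ua[1] * g2;
    F[6] += ua[2] * g0; F[7] += ua[2] * g1; F[8] += ua[2] * g2;
  }
  // cofactor matrix C: F^{-T} = C / J
  double C0 = F[4] * F[8] - F[5] * F[7];
  double C1 = F[5] * F[6] - F[3] * F[8];
  double C2 = F[3] * F[7] - F[4] * F[6];
  double C3 = F[2] * F[7] - F[1] * F[8];
  double C4 = F[0] * F[8] - F[2] * F[6];
  double C5 = F[1] * F[6] - F[0] * F[7];
  double C6 = F[1] * F[5] - F[2] * F[4];
  double C7 = F[2] * F[3] - F[0] * F[5];
  double C8 = F[0] * F[4] - F[1] * F[3];
  double J = F[0] * C0 + F[1] * C1 + F[2] * C2;
  *Jout = J;
  // jclamp > 0: regularised transient extension — the singular 1/J factors
  // are evaluated at max(J, jclamp) so near-collapse excursions produce
  // large finite restoring forces instead of failing; the volumetric
  // pressure keeps the true J. jclamp = 0: strict (error on inversion).
  double Jc = J;
  if (jclamp > 0.0) {
    if (J < jclamp) Jc = jclamp;
  } else if (!(J > 1e-9)) {
    return false;
  }
  double I1 = 0.0;
  for (int q = 0; q < 9; ++q) I1 += F[q] * F[q];
  double Jm23 = 1.0 / std::cbrt(Jc * Jc);
  double c1 = mu * Jm23;
  double c2 = -c1 * (I1 / 3.0) / Jc + kappa * (J - 1.0);  // exact zero at F = I
  double P[9];
  double Cm[9] = {C0, C1, C2, C3, C4, C5, C6, C7, C8};
  for (int q = 0; q < 9; ++q) P[q] = c1 * F[q] + c2 * Cm[q];
  if (!std::isfinite(P[0])) return false;
  *Wout = 0.5 * mu * (Jm23 * I1 - 3.0) + 0.5 * kappa * (J - 1.0) * (J - 1.0);
  for (int t = lo; t < hi; ++t) {
    double* fa = f3 + 3 * idx[t];
    double g0 = gx[t], g1 = gy[t], g2 = gz[t];
    fa[0] += wq * (P[0] * g0 + P[1] * g1 + P[2] * g2);
    fa[1] += wq * (P[3] * g0 + P[4] * g1 + P[5] * g2);
    fa[2] += wq * (P[6] * g0 + P[7] * g1 + P[8] * g2);
  }
  return true;
}

// [[Rcpp::export]]
List cpp_internal_forces(NumericMatrix u, IntegerVector ptr, IntegerVector idx0,
                         NumericVector gx, NumericVector gy, NumericVector gz,
                         NumericVector wq, NumericVector mu,
                         NumericVector kappa) {
  const int n = u.nrow();
  const int n_ip = wq.size();
  std::vector<double> u3((size_t)3 * n), f3((size_t)3 * n, 0.0);
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c) u3[3 * a + c] = u[a + (R_xlen_t)n * c];
  double Wtot = 0.0, Jmin = R_PosInf;
  int bad = 0;
  for (int ip = 0; ip < n_ip; ++ip) {
    double W = 0.0, J = 0.0;
    bool ok = ip_force3(&u3[0], idx0.begin(), gx.begin(), gy.begin(),
                        gz.begin(), ptr[ip], ptr[ip + 1], wq[ip], mu[ip],
                        kappa[ip], &f3[0], &W, &J);
    if (!ok) { bad = ip + 1; break; }
    if (J < Jmin) Jmin = J;
    Wtot += wq[ip] * W;
  }
  NumericMatrix f(n, 3);
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c) f[a + (R_xlen_t)n * c] = f3[3 * a + c];
  return List::create(_["f"] = f, _["energy"] = Wtot, _["J_min"] = Jmin,
                      _["bad_ip"] = bad);
}

// ---------------------------------------------------------------------------
// Damped central-difference relaxation loop (dynamic relaxation).
// u in mm, mass in kg, forces mN -> accelerations mm/s^2.
// Constraints: DOF list (0-based dof = node + n*component) pinned to targets.
// Converged when the max nodal displacement increment over a `window`-step
// interval falls below tol.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_relax(NumericMatrix u0, IntegerVector ptr, IntegerVector idx0,
               NumericVector gx, NumericVector gy, NumericVector gz,
               NumericVector wq, NumericVector mu, NumericVector kappa,
               NumericVector mass, double dt, double alpha,
               IntegerVector con_dof, NumericVector con_target, double tol,
               int window, int max_iter, bool adaptive, int ramp) {
  const int n = u0.nrow();
  const int n_ip = wq.size();
  const int ncon = con_dof.size();
  // interleaved layout: index 3*node + component
  std::vector<double> u((size_t)3 * n), minv((size_t)3 * n);
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c) {
      u[3 * a + c] = u0[a + (R_xlen_t)n * c];
      minv[3 * a + c] = 1.0 / mass[a];
    }
  std::vector<int> cdof(ncon);
  for (int c = 0; c < ncon; ++c) {
    int d = con_dof[c];
    cdof[c] = 3 * (d % n) + d / n;
  }
  std::vector<double> v((size_t)3 * n, 0.0);
  std::vector<double> f((size_t)3 * n, 0.0);
  std::vector<double> uref(u);
  std::vector<double> fref((size_t)3 * n, 0.0);
  bool have_fref = false;
  double cfac = 0.5 * alpha * dt;
  int iter = 0, bad = 0;
  bool converged = false, diverged = false;
  double final_incr = NA_REAL;
#if defined(__SSE2__)
  // exponentially decaying velocities cross into subnormal range and slow
  // the arithmetic by ~5x; flush-to-zero for the duration of the loop
  unsigned int csr_saved = _mm_getcsr();
  _mm_setcsr(csr_saved | 0x8040);  // FTZ | DAZ
#endif
  // prescribed motion is ramped linearly over the first `ramp` steps to
  // avoid constraint shock (an instantaneous jump next to a pre-strained
  // stiff region can invert elements outright)
  std::vector<double> tgt0(ncon);
  for (int c = 0; c < ncon; ++c) tgt0[c] = u[cdof[c]];
  if (ramp < 1) {
    for (int c = 0; c < ncon; ++c) u[cdof[c]] = con_target[c];
  }
  const int* ptrp = ptr.begin();
  const int* idxp = idx0.begin();
  const double* gxp = gx.begin(); const double* gyp = gy.begin();
  const double* gzp = gz.begin();
  const double* wqp = wq.begin(); const double* mup = mu.begin();
  const double* kap = kappa.begin();
  while (iter < max_iter) {
    std::fill(f.begin(), f.end(), 0.0);
    for (int ip = 0; ip < n_ip; ++ip) {
      double W, J;
      bool ok = ip_force3(&u[0], idxp, gxp, gyp, gzp, ptrp[ip], ptrp[ip + 1],
                          wqp[ip], mup[ip], kap[ip], &f[0], &W, &J);
      if (!ok) { bad = ip + 1; break; }
    }
    if (bad) break;
    const double vfac = (1.0 - cfac) / (1.0 + cfac);
    const double afac = dt / (1.0 + cfac);
    for (int d = 0; d < 3 * n; ++d) {
      double vn = vfac * v[d] - afac * f[d] * minv[d];
      v[d] = vn;
      u[d] += dt * vn;
    }
    double frac = (ramp > 0 && iter < ramp)
        ? (double)(iter + 1) / (double)ramp : 1.0;
    for (int c = 0; c < ncon; ++c) {
      int d = cdof[c];
      u[d] = tgt0[c] + frac * (con_target[c] - tgt0[c]);
      v[d] = 0.0;
    }
    ++iter;
    if (iter % window == 0 && iter >= ramp) {
      double mx = 0.0;
      bool finite = true;
      for (int d = 0; d < 3 * n; ++d) {
        double dd = std::fabs(u[d] - uref[d]);
        if (!std::isfinite(u[d])) { finite = false; break; }
        if (dd > mx) mx = dd;
      }
      if (!finite) { diverged = true; break; }
      // kill residual subnormal velocities (portable backstop to FTZ)
      for (int d = 0; d < 3 * n; ++d)
        if (std::fabs(v[d]) < 1e-100) v[d] = 0.0;
      final_incr = mx;
      if (mx <= tol) { converged = true; break; }
      if (adaptive) {
        // Rayleigh-quotient estimate of the slowest active mode over the
        // last window: omega^2 = du.df / du.M.du, damping alpha = 2 omega
        // (standard dynamic-relaxation tuning). Constrained dofs have
        // du = 0 and drop out.
        if (have_fref) {
          double num = 0.0, den = 0.0;
          for (int d = 0; d < 3 * n; ++d) {
            double du = u[d] - uref[d];
            num += du * (f[d] - fref[d]);
            den += du * du / minv[d];
          }
          if (num > 0.0 && den > 0.0) {
            double omega = std::sqrt(num / den);
            double a_new = 2.0 * omega;
            double a_cap = 1.0 / dt;   // keep the update well-posed
            double a_floor = 1e-3 / dt;
            if (a_new > a_cap) a_new = a_cap;
            if (a_new < a_floor) a_new = a_floor;
            cfac = 0.5 * a_new * dt;
          }
        }
        std::copy(f.begin(), f.end(), fref.begin());
        have_fref = true;
      }
      std::copy(u.begin(), u.end(), uref.begin());
    }
  }
#if defined(__SSE2__)
  _mm_setcsr(csr_saved);
#endif
  // validate the final state: the last update is otherwise unchecked and
  // could hand an inverted configuration to the next increment
  if (!bad && !diverged) {
    for (int ip = 0; ip < n_ip; ++ip) {
      double W, J;
      if (!ip_force3(&u[0], idxp, gxp, gyp, gzp, ptrp[ip], ptrp[ip + 1],
                     0.0, mup[ip], kap[ip], &f[0], &W, &J)) {
        bad = ip + 1;
        break;
      }
    }
  }
  double ke = 0.0;
  for (int d = 0; d < 3 * n; ++d) ke += 0.5 * v[d] * v[d] / minv[d];
  NumericMatrix uout(n, 3), vout(n, 3);
  for (int a = 0; a < n; ++a)
    for (int c = 0; c < 3; ++c) {
      uout[a + (R_xlen_t)n * c] = u[3 * a + c];
      vout[a + (R_xlen_t)n * c] = v[3 * a + c];
    }
  return List::create(_["u"] = uout, _["v"] = vout, _["iterations"] = iter,
                      _["converged"] = converged, _["diverged"] = diverged,
                      _["final_incr"] = final_incr, _["kinetic_energy"] = ke,
                      _["bad_ip"] = bad, _["alpha_final"] = 2.0 * cfac / dt);
}

// Single damped central-difference step (same update rule as cpp_relax).
// [[Rcpp::export]]
List cpp_step(NumericMatrix u, NumericMatrix v, NumericMatrix f,
              NumericVector mass, double dt, double alpha,
              IntegerVector con_dof, NumericVector con_target) {
  const int n = u.nrow();
  NumericMatrix uo(n, 3), vo(n, 3);
  const double cfac = 0.5 * alpha * dt;
  for (int d = 0; d < 3 * n; ++d) {
    int node = d % n;
    double a = -f[d] / mass[node];
    double vn = ((1.0 - cfac) * v[d] + dt * a) / (1.0 + cfac);
    vo[d] = vn;
    uo[d] = u[d] + dt * vn;
  }
  for (int c = 0; c < con_dof.size(); ++c) {
    int d = con_dof[c];
    uo[d] = con_target[c];
    vo[d] = 0.0;
  }
  return List::create(_["u"] = uo, _["v"] = vo);
}

// ---------------------------------------------------------------------------
// Voxel occupancy of the convex support-function envelope of a point cloud.
// A voxel centre c is inside iff  dot(c, d) <= max_i dot(P_i, d) + offset
// for every direction d in a quasi-uniform set. Voxel order: x fastest.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_support_occupancy(NumericMatrix pts, NumericMatrix dirs,
                                    NumericVector origin, double voxel,
                                    IntegerVector dims, double offset) {
  const int np = pts.nrow(), nd = dirs.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> smax(nd, -1e300);
  for (int d = 0; d < nd; ++d) {
    double dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    double s = -1e300;
    for (int i = 0; i < np; ++i) {
      double t = pts(i, 0) * dx + pts(i, 1) * dy + pts(i, 2) * dz;
      if (t > s) s = t;
    }
    smax[d] = s + offset;
  }
  // cheap bounding-box reject
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int i = 0; i < np; ++i)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], pts(i, a));
      hi[a] = std::max(hi[a], pts(i, a));
    }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k) {
    double cz = origin[2] + k * voxel;
    for (int j = 0; j < ny; ++j) {
      double cy = origin[1] + j * voxel;
      for (int i = 0; i < nx; ++i, ++q) {
        double cx = origin[0] + i * voxel;
        if (cx < lo[0] - offset || cx > hi[0] + offset ||
            cy < lo[1] - offset || cy > hi[1] + offset ||
            cz < lo[2] - offset || cz > hi[2] + offset) {
          out[q] = false;
          continue;
        }
        bool inside = true;
        for (int d = 0; d < nd; ++d) {
          if (cx * dirs(d, 0) + cy * dirs(d, 1) + cz * dirs(d, 2) > smax[d]) {
            inside = false;
            break;
          }
        }
        out[q] = inside;
      }
    }
  }
  return out;
}
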