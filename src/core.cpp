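// Compiled kernels: 3D Euclidean distance transform, sphere-fitting local
// thickness, 26-connected component labeling, and an element-by-element
// preconditioned conjugate-gradient solver for the voxel hexahedral micro-FE
// problem. All arrays are column-major with dim = c(nx, ny, nz).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---- 1D squared-distance lower-envelope transform (Felzenszwalb & Huttenlocher)
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue; // infinite parabolas never form the envelope
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k >= 0 && s <= z[k]) {
      --k;
      if (k >= 0)
        s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
            (2.0 * q - 2.0 * v[k]);
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; }
    else { ++k; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  if (k < 0) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared EDT: distance (in voxels) from every voxel to the nearest feature
// (TRUE) voxel. Voxels inside the feature set get 0.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = feature[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)j * nx];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)j * nx] = d[j];
    }
  // along z
  R_xlen_t slab = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (R_xlen_t)k * slab];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; ++k) g[base + (R_xlen_t)k * slab] = d[k];
    }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = g[i];
  return out;
}

// Hildebrand local thickness by maximal-sphere filling: thickness(x) = 2 r of
// the largest inscribed sphere (within the mask) containing x. `radius` is the
// inscribed-sphere radius at each voxel, in voxels (sqrt of EDT to background).
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, NumericVector radius,
                                  IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> th(n, 0.0);
  R_xlen_t slab = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)k * slab + (R_xlen_t)j * nx + i;
        if (!mask[idx]) continue;
        double r = radius[idx];
        if (r <= 0) continue;
        double r2 = r * r;
        int ir = (int)std::floor(r);
        int k0 = std::max(0, k - ir), k1 = std::min(nz - 1, k + ir);
        int j0 = std::max(0, j - ir), j1 = std::min(ny - 1, j + ir);
        int i0 = std::max(0, i - ir), i1 = std::min(nx - 1, i + ir);
        double dia = 2.0 * r;
        for (int kk = k0; kk <= k1; ++kk) {
          double dz2 = (double)(kk - k) * (kk - k);
          for (int jj = j0; jj <= j1; ++jj) {
            double dyz2 = dz2 + (double)(jj - j) * (jj - j);
            if (dyz2 > r2) continue;
            R_xlen_t row = (R_xlen_t)kk * slab + (R_xlen_t)jj * nx;
            for (int ii = i0; ii <= i1; ++ii) {
              if (dyz2 + (double)(ii - i) * (ii - i) <= r2) {
                R_xlen_t t = row + ii;
                if (mask[t] && th[t] < dia) th[t] = dia;
              }
            }
          }
        }
      }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = th[i];
  return out;
}

// 26-connected component labeling of a logical 3D mask. Labels start at 1;
// background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  R_xlen_t slab = (R_xlen_t)nx * ny;
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int pk = (int)(p / slab);
      int pj = (int)((p - (R_xlen_t)pk * slab) / nx);
      int pi = (int)(p - (R_xlen_t)pk * slab - (R_xlen_t)pj * nx);
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = pk + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = pj + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = pi + di; if (ii < 0 || ii >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            R_xlen_t q = (R_xlen_t)kk * slab + (R_xlen_t)jj * nx + ii;
            if (mask[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
          }
        }
      }
    }
  }
  return lab;
}

// ---- micro-FE: element-by-element matvec y = A x with A = sum_e E_e K0
static void ebe_matvec(const IntegerMatrix& edof, const NumericVector& Evec,
                       const NumericMatrix& K0, const std::vector<double>& x,
                       std::vector<double>& y) {
  int nel = edof.ncol();
  std::fill(y.begin(), y.end(), 0.0);
  double xe[24], ye[24];
  const double* K = K0.begin(); // 24 x 24 column-major
  for (int e = 0; e < nel; ++e) {
    const int* dof = &edof(0, e);
    for (int a = 0; a < 24; ++a) xe[a] = x[dof[a]];
    for (int a = 0; a < 24; ++a) ye[a] = 0.0;
    for (int b = 0; b < 24; ++b) {
      double xb = xe[b];
      if (xb == 0.0) continue;
      const double* col = K + 24 * b;
      for (int a = 0; a < 24; ++a) ye[a] += col[a] * xb;
    }
    double E = Evec[e];
    for (int a = 0; a < 24; ++a) y[dof[a]] += E * ye[a];
  }
}

// Jacobi-preconditioned CG on the constrained system. `fixed` marks Dirichlet
// dofs whose values are given in `ufix`; `x0` is a warm start for free dofs.
// [[Rcpp::export]]
List cpp_fe_solve(IntegerMatrix edof, NumericVector Evec, NumericMatrix K0,
                  int ndof, LogicalVector fixed, NumericVector ufix,
                  NumericVector x0, double rtol, int maxit) {
  std::vector<double> u(ndof), r(ndof), zv(ndof), p(ndof), Ap(ndof), diag(ndof, 0.0);
  int nel = edof.ncol();
  for (int e = 0; e < nel; ++e) {
    double E = Evec[e];
    for (int a = 0; a < 24; ++a) diag[edof(a, e)] += E * K0(a, a);
  }
  // rhs = -A * u_c restricted to free dofs (zero body force)
  std::vector<double> uc(ndof, 0.0);
  for (int i = 0; i < ndof; ++i) if (fixed[i]) uc[i] = ufix[i];
  std::vector<double> b(ndof);
  ebe_matvec(edof, Evec, K0, uc, b);
  for (int i = 0; i < ndof; ++i) b[i] = fixed[i] ? 0.0 : -b[i];
  double bnorm = 0.0;
  for (int i = 0; i < ndof; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  // start from warm start on free dofs
  for (int i = 0; i < ndof; ++i) u[i] = fixed[i] ? 0.0 : x0[i];
  ebe_matvec(edof, Evec, K0, u, r);
  for (int i = 0; i < ndof; ++i) r[i] = fixed[i] ? 0.0 : b[i] - r[i];
  double rnorm = 0.0;
  for (int i = 0; i < ndof; ++i) rnorm += r[i] * r[i];
  rnorm = std::sqrt(rnorm);
  double tol = rtol * (bnorm > 0 ? bnorm : 1.0);
  int it = 0;
  if (rnorm > tol) {
    double rz = 0.0;
    for (int i = 0; i < ndof; ++i) {
      zv[i] = fixed[i] ? 0.0 : r[i] / (diag[i] > 0 ? diag[i] : 1.0);
      rz += r[i] * zv[i];
    }
    p = zv;
    for (it = 1; it <= maxit; ++it) {
      ebe_matvec(edof, Evec, K0, p, Ap);
      double pAp = 0.0;
      for (int i = 0; i < ndof; ++i) { if (fixed[i]) Ap[i] = 0.0; else pAp += p[i] * Ap[i]; }
      if (pAp <= 0) break;
      double alpha = rz / pAp;
      rnorm = 0.0;
      for (int i = 0; i < ndof; ++i) {
        u[i] += alpha * p[i];
        r[i] -= alpha * Ap[i];
        rnorm += r[i] * r[i];
      }
      rnorm = std::sqrt(rnorm);
      if (rnorm <= tol) break;
      double rznew = 0.0;
      for (int i = 0; i < ndof; ++i) {
        zv[i] = fixed[i] ? 0.0 : r[i] / (diag[i] > 0 ? diag[i] : 1.0);
        rznew += r[i] * zv[i];
      }
      double beta = rznew / rz;
      rz = rznew;
      for (int i = 0; i < ndof; ++i) p[i] = zv[i] + beta * p[i];
    }
  }
  NumericVector uu(ndof);
  for (int i = 0; i < ndof; ++i) uu[i] = fixed[i] ? ufix[i] : u[i];
  return List::create(_["u"] = uu, _["iters"] = it,
                      _["relres"] = bnorm > 0 ? rnorm / bnorm : 0.0);
}

// Per-element quadratic form q_e = u_e' K0 u_e (independent of E scaling).
// [[Rcpp::export]]
NumericVector cpp_fe_element_energy(IntegerMatrix edof, NumericMatrix K0,
                                    NumericVector u) {
  int nel = edof.ncol();
  NumericVector q(nel);
  double xe[24], ye[24];
  const double* K = K0.begin();
  for (int e = 0; e < nel; ++e) {
    const int* dof = &edof(0, e);
    for (int a = 0; a < 24; ++a) xe[a] = u[dof[a]];
    for (int a = 0; a < 24; ++a) ye[a] = 0.0;
    for (int b = 0; b < 24; ++b) {
      double xb = xe[b];
      if (xb == 0.0) continue;
      const double* col = K + 24 * b;
      for (int a = 0; a < 24; ++a) ye[a] += col[a] * xb;
    }
    double s = 0.0;
    for (int a = 0; a < 24; ++a) s += xe[a] * ye[a];
    q[e] = s;
  }
  return q;
}
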