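#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

// Conjugate-gradient solver for the 7-point variable-coefficient stencil
//
//   (A x)_i = d_i x_i + sum_{faces f=(i,j)} w_f (x_i - x_j)
//
// on an nx * ny * nz voxel grid (column-major, x fastest). Face weight
// arrays wx, wy, wz have one entry per interior face: wx is
// (nx-1) x ny x nz, etc. Voxels flagged in `fixed` hold Dirichlet values
// (`fixed_values`); their rows/columns are eliminated symmetrically so
// the reduced operator stays SPD, and their values feed the right-hand
// side. Jacobi (diagonal) preconditioning. Deterministic.
//
// For speed the stencil is converted once into per-voxel neighbour
// weights (wm*/wp* = weight to the -/+ neighbour along each axis, zeroed
// at domain boundaries and towards fixed voxels), so the matvec is a
// single branch-free sweep.

static inline long idx3(int i, int j, int k, int nx, int ny) {
  return i + (long)nx * (j + (long)ny * k);
}

// [[Rcpp::export(name = ".cg_stencil_solve")]]
List cg_stencil_solve(IntegerVector dim,
                      NumericVector wx, NumericVector wy, NumericVector wz,
                      NumericVector dextra,
                      IntegerVector fixed, NumericVector fixed_values,
                      NumericVector b, NumericVector x0,
                      double tol, int maxit) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  if (wx.size() != (R_xlen_t)(nx - 1) * ny * nz ||
      wy.size() != (R_xlen_t)nx * (ny - 1) * nz ||
      wz.size() != (R_xlen_t)nx * ny * (nz - 1))
    stop("face weight arrays do not match grid dimensions");

  const double* pwx = wx.begin();
  const double* pwy = wy.begin();
  const double* pwz = wz.begin();
  const double* pde = dextra.begin();
  const int* pfix = fixed.begin();
  const double* pg = fixed_values.begin();
  const double* pb = b.begin();
  const double* px0 = x0.begin();

  // Per-voxel neighbour weights (0 across domain boundaries and between
  // fixed voxels), diagonal, and RHS with Dirichlet contributions.
  std::vector<double> wmx(n, 0.0), wpx(n, 0.0), wmy(n, 0.0), wpy(n, 0.0),
      wmz(n, 0.0), wpz(n, 0.0), D(n, 1.0), rhs(n, 0.0), x(n, 0.0);
  std::vector<char> fr(n, 0);  // free voxel flag
  const int nxm = nx - 1;
  long n_free = 0;

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const long id = idx3(i, j, k, nx, ny);
        if (pfix[id]) { x[id] = pg[id]; continue; }
        fr[id] = 1; ++n_free;
        double d = pde[id], rh = pb[id];
        double w;
        if (i > 0) {
          w = pwx[(i - 1) + (long)nxm * (j + (long)ny * k)];
          d += w;
          if (pfix[id - 1]) rh += w * pg[id - 1]; else wmx[id] = w;
        }
        if (i < nx - 1) {
          w = pwx[i + (long)nxm * (j + (long)ny * k)];
          d += w;
          if (pfix[id + 1]) rh += w * pg[id + 1]; else wpx[id] = w;
        }
        if (j > 0) {
          w = pwy[i + (long)nx * ((j - 1) + (long)(ny - 1) * k)];
          d += w;
          if (pfix[id - nx]) rh += w * pg[id - nx]; else wmy[id] = w;
        }
        if (j < ny - 1) {
          w = pwy[i + (long)nx * (j + (long)(ny - 1) * k)];
          d += w;
          if (pfix[id + nx]) rh += w * pg[id + nx]; else wpy[id] = w;
        }
        if (k > 0) {
          w = pwz[i + (long)nx * (j + (long)ny * (k - 1))];
          d += w;
          if (pfix[id - (long)nx * ny]) rh += w * pg[id - (long)nx * ny];
          else wmz[id] = w;
        }
        if (k < nz - 1) {
          w = pwz[i + (long)nx * (j + (long)ny * k)];
          d += w;
          if (pfix[id + (long)nx * ny]) rh += w * pg[id + (long)nx * ny];
          else wpz[id] = w;
        }
        if (d <= 0.0) d = 1e-300;  // isolated voxel (all faces zero weight)
        D[id] = d; rhs[id] = rh; x[id] = px0[id];
      }

  const long sx = 1, sy = nx, sz = (long)nx * ny;
  // y = A v on the free subspace (weights to fixed/boundary voxels are 0,
  // so the sweep needs no branches beyond the edge guards).
  auto matvec = [&](const double* v, double* y) {
    for (long id = 0; id < n; ++id) {
      if (!fr[id]) { y[id] = 0.0; continue; }
      double acc = D[id] * v[id];
      if (wmx[id] != 0.0) acc -= wmx[id] * v[id - sx];
      if (wpx[id] != 0.0) acc -= wpx[id] * v[id + sx];
      if (wmy[id] != 0.0) acc -= wmy[id] * v[id - sy];
      if (wpy[id] != 0.0) acc -= wpy[id] * v[id + sy];
      if (wmz[id] != 0.0) acc -= wmz[id] * v[id - sz];
      if (wpz[id] != 0.0) acc -= wpz[id] * v[id + sz];
      y[id] = acc;
    }
  };

  double bnorm = 0.0;
  for (long id = 0; id < n; ++id) if (fr[id]) bnorm += rhs[id] * rhs[id];
  bnorm = std::sqrt(bnorm);
  const double atol = tol * (bnorm > 0.0 ? bnorm : 1.0);

  std::vector<double> r(n, 0.0), z(n, 0.0), p(n, 0.0), q(n, 0.0);
  std::vector<double> resid_hist;
  int iters = 0;
  bool converged = false;

  matvec(x.data(), q.data());
  double rz = 0.0, rnorm = 0.0;
  for (long id = 0; id < n; ++id) {
    if (!fr[id]) continue;
    r[id] = rhs[id] - q[id];
    z[id] = r[id] / D[id];
    p[id] = z[id];
    rz += r[id] * z[id];
    rnorm += r[id] * r[id];
  }
  rnorm = std::sqrt(rnorm);
  resid_hist.push_back(bnorm > 0 ? rnorm / bnorm : rnorm);
  if (rnorm <= atol || n_free == 0) converged = true;

  while (!converged && iters < maxit) {
    matvec(p.data(), q.data());
    double pq = 0.0;
    for (long id = 0; id < n; ++id) if (fr[id]) pq += p[id] * q[id];
    if (pq <= 0.0) break;  // exact solve reached / numerically singular
    const double alpha = rz / pq;
    rnorm = 0.0;
    for (long id = 0; id < n; ++id) {
      if (!fr[id]) continue;
      x[id] += alpha * p[id];
      r[id] -= alpha * q[id];
      rnorm += r[id] * r[id];
    }
    rnorm = std::sqrt(rnorm);
    ++iters;
    resid_hist.push_back(bnorm > 0 ? rnorm / bnorm : rnorm);
    if (rnorm <= atol) { converged = true; break; }
    double rz_new = 0.0;
    for (long id = 0; id < n; ++id)
      if (fr[id]) { z[id] = r[id] / D[id]; rz_new += r[id] * z[id]; }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (long id = 0; id < n; ++id)
      if (fr[id]) p[id] = z[id] + beta * p[id];
  }

  NumericVector xout(n);
  std::memcpy(xout.begin(), x.data(), n * sizeof(double));
  return List::create(_["x"] = xout,
                      _["iterations"] = iters,
                      _["residuals"] = NumericVector(resid_hist.begin(),
                                                     resid_hist.end()),
                      _["converged"] = converged);
}
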