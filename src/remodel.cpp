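// Compiled kernels: rigid resampling, 6-connectivity morphology/labelling,
// and the matrix-free voxel hexahedral FE solver.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Rigid resampling
// ---------------------------------------------------------------------------

// Catmull-Rom cubic convolution weights for offsets k = -1, 0, 1, 2
static inline double cubw(double t, int k) {
  switch (k) {
  case -1: return 0.5 * ((2.0 - t) * t - 1.0) * t;
  case 0:  return 0.5 * (t * t * (3.0 * t - 5.0) + 2.0);
  case 1:  return 0.5 * ((4.0 - 3.0 * t) * t + 1.0) * t;
  default: return 0.5 * (t - 1.0) * t * t;
  }
}

static inline int iclamp(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// snap continuous indices that are within 1e-9 voxel of an integer, so exact
// identity/integer-voxel transforms reproduce grid values bitwise
static inline double isnap(double u) {
  const double r = std::nearbyint(u);
  return std::fabs(u - r) < 1e-9 ? r : u;
}

// Pull-back resampling on the input grid: out(x) = in(A x + b), where x is the
// physical position of each output voxel centre. interp: 0 nearest, 1 linear,
// 3 cubic. Out-of-domain samples get `fill` (may be NA).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vals, IntegerVector dim, double sp,
                           NumericVector origin, NumericMatrix A,
                           NumericVector shift, int interp, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double a11 = A(0,0), a12 = A(0,1), a13 = A(0,2);
  const double a21 = A(1,0), a22 = A(1,1), a23 = A(1,2);
  const double a31 = A(2,0), a32 = A(2,1), a33 = A(2,2);
  const double b1 = shift[0], b2 = shift[1], b3 = shift[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double *v = vals.begin();
  double *o = out.begin();
  R_xlen_t idx = 0;
  for (int iz = 0; iz < nz; ++iz) {
    const double pz = oz + iz * sp;
    for (int iy = 0; iy < ny; ++iy) {
      const double py = oy + iy * sp;
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        const double px = ox + ix * sp;
        const double qx = a11 * px + a12 * py + a13 * pz + b1;
        const double qy = a21 * px + a22 * py + a23 * pz + b2;
        const double qz = a31 * px + a32 * py + a33 * pz + b3;
        const double ux = isnap((qx - ox) / sp);
        const double uy = isnap((qy - oy) / sp);
        const double uz = isnap((qz - oz) / sp);
        if (interp == 0) {
          const int jx = (int)std::lround(ux), jy = (int)std::lround(uy),
                    jz = (int)std::lround(uz);
          if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz) {
            o[idx] = fill;
          } else {
            o[idx] = v[jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz)];
          }
        } else if (ux < 0 || ux > nx - 1 || uy < 0 || uy > ny - 1 ||
                   uz < 0 || uz > nz - 1) {
          o[idx] = fill;
        } else if (interp == 1) {
          int jx = (int)std::floor(ux), jy = (int)std::floor(uy),
              jz = (int)std::floor(uz);
          jx = iclamp(jx, 0, nx - 2); jy = iclamp(jy, 0, ny - 2);
          jz = iclamp(jz, 0, nz - 2);
          const double tx = ux - jx, ty = uy - jy, tz = uz - jz;
          double acc = 0.0;
          for (int dz = 0; dz <= 1; ++dz) {
            const double wz = dz ? tz : 1.0 - tz;
            for (int dy = 0; dy <= 1; ++dy) {
              const double wy = dy ? ty : 1.0 - ty;
              for (int dx = 0; dx <= 1; ++dx) {
                const double wx = dx ? tx : 1.0 - tx;
                acc += wx * wy * wz *
                  v[(jx + dx) + (R_xlen_t)nx * ((jy + dy) + (R_xlen_t)ny * (jz + dz))];
              }
            }
          }
          o[idx] = acc;
        } else {
          const int jx = (int)std::floor(ux), jy = (int)std::floor(uy),
                    jz = (int)std::floor(uz);
          const double tx = ux - jx, ty = uy - jy, tz = uz - jz;
          double acc = 0.0;
          for (int dz = -1; dz <= 2; ++dz) {
            const double wz = cubw(tz, dz);
            const int kz = iclamp(jz + dz, 0, nz - 1);
            for (int dy = -1; dy <= 2; ++dy) {
              const double wy = cubw(ty, dy);
              const int ky = iclamp(jy + dy, 0, ny - 1);
              for (int dx = -1; dx <= 2; ++dx) {
                const int kx = iclamp(jx + dx, 0, nx - 1);
                acc += cubw(tx, dx) * wy * wz *
                  v[kx + (R_xlen_t)nx * (ky + (R_xlen_t)ny * kz)];
              }
            }
          }
          o[idx] = acc;
        }
      }
    }
  }
  return out;
}

// Fused rigid-MSE kernel: mean squared error between `fixed` and the
// linearly interpolated pull-back of `moving` through x -> A x + b, sampled
// on a strided subgrid. Returns (mse, in-domain fraction). No allocation.
// [[Rcpp::export]]
NumericVector cpp_mse_rigid(NumericVector fixed, NumericVector moving,
                            IntegerVector dim, double sp,
                            NumericVector origin, NumericMatrix A,
                            NumericVector shift, int stride) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double a11 = A(0,0), a12 = A(0,1), a13 = A(0,2);
  const double a21 = A(1,0), a22 = A(1,1), a23 = A(1,2);
  const double a31 = A(2,0), a32 = A(2,1), a33 = A(2,2);
  const double b1 = shift[0], b2 = shift[1], b3 = shift[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double *f = fixed.begin();
  const double *v = moving.begin();
  double sse = 0.0;
  R_xlen_t n_in = 0, n_tot = 0;
  for (int iz = 0; iz < nz; iz += stride) {
    const double pz = oz + iz * sp;
    for (int iy = 0; iy < ny; iy += stride) {
      const double py = oy + iy * sp;
      for (int ix = 0; ix < nx; ix += stride) {
        ++n_tot;
        const double px = ox + ix * sp;
        const double ux = isnap((a11 * px + a12 * py + a13 * pz + b1 - ox) / sp);
        const double uy = isnap((a21 * px + a22 * py + a23 * pz + b2 - oy) / sp);
        const double uz = isnap((a31 * px + a32 * py + a33 * pz + b3 - oz) / sp);
        if (ux < 0 || ux > nx - 1 || uy < 0 || uy > ny - 1 ||
            uz < 0 || uz > nz - 1)
          continue;
        int jx = iclamp((int)std::floor(ux), 0, nx - 2);
        int jy = iclamp((int)std::floor(uy), 0, ny - 2);
        int jz = iclamp((int)std::floor(uz), 0, nz - 2);
        const double tx = ux - jx, ty = uy - jy, tz = uz - jz;
        const R_xlen_t base = jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
        const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
        const double c00 = v[base] * (1 - tx) + v[base + sx] * tx;
        const double c10 = v[base + sy] * (1 - tx) + v[base + sy + sx] * tx;
        const double c01 = v[base + sz] * (1 - tx) + v[base + sz + sx] * tx;
        const double c11 = v[base + sz + sy] * (1 - tx) + v[base + sz + sy + sx] * tx;
        const double c0 = c00 * (1 - ty) + c10 * ty;
        const double c1 = c01 * (1 - ty) + c11 * ty;
        const double val = c0 * (1 - tz) + c1 * tz;
        const double dfv = f[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] - val;
        sse += dfv * dfv;
        ++n_in;
      }
    }
  }
  NumericVector out(2);
  out[0] = n_in > 0 ? sse / n_in : R_PosInf;
  out[1] = n_tot > 0 ? (double)n_in / n_tot : 0.0;
  return out;
}

// ---------------------------------------------------------------------------
// 6-connectivity labelling and morphology
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int *m = mask.begin();
  int *L = lab.begin();
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (m[s] != 1 || L[s] != 0) continue;
    ++cur;
    stack.push_back(s);
    L[s] = cur;
    while (!stack.empty()) {
      const R_xlen_t p = stack.back();
      stack.pop_back();
      const int ix = (int)(p % nx);
      const int iy = (int)((p / nx) % ny);
      const int iz = (int)(p / ((R_xlen_t)nx * ny));
      const int dxs[6] = {-1, 1, 0, 0, 0, 0};
      const int dys[6] = {0, 0, -1, 1, 0, 0};
      const int dzs[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        const int jx = ix + dxs[k], jy = iy + dys[k], jz = iz + dzs[k];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        const R_xlen_t q = jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
        if (m[q] == 1 && L[q] == 0) {
          L[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// One 6-neighbourhood dilation (dilate = true) or erosion pass, repeated
// `iters` times. `border` is the value assumed outside the grid.
// [[Rcpp::export]]
LogicalVector cpp_morph6(LogicalVector mask, IntegerVector dim, int iters,
                         bool dilate, bool border) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> cur(n), nxt(n);
  for (R_xlen_t i = 0; i < n; ++i) cur[i] = (char)(mask[i] == 1);
  const int dxs[6] = {-1, 1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, -1, 1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, -1, 1};
  for (int it = 0; it < iters; ++it) {
    R_xlen_t p = 0;
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix, ++p) {
          char acc = cur[p];
          if (dilate ? acc : !acc) { nxt[p] = acc; continue; }
          for (int k = 0; k < 6; ++k) {
            const int jx = ix + dxs[k], jy = iy + dys[k], jz = iz + dzs[k];
            char nb;
            if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
              nb = (char)border;
            else
              nb = cur[jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz)];
            if (dilate && nb) { acc = 1; break; }
            if (!dilate && !nb) { acc = 0; break; }
          }
          nxt[p] = acc;
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (int)cur[i];
  return out;
}

// ---------------------------------------------------------------------------
// Voxel hexahedral finite elements
// ---------------------------------------------------------------------------

// Local node ordering: lexicographic voxel corners, x fastest:
// (0,0,0) (1,0,0) (0,1,0) (1,1,0) (0,0,1) (1,0,1) (0,1,1) (1,1,1).
static void hex_B(double xi, double eta, double zeta, double h, double B[6][24]) {
  static const int sgn[8][3] = {
    {-1,-1,-1}, {1,-1,-1}, {-1,1,-1}, {1,1,-1},
    {-1,-1, 1}, {1,-1, 1}, {-1,1, 1}, {1,1, 1}};
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 24; ++c) B[r][c] = 0.0;
  const double s = 2.0 / h; // d(xi)/d(x) for a cube of edge h
  for (int i = 0; i < 8; ++i) {
    const double sx = sgn[i][0], sy = sgn[i][1], sz = sgn[i][2];
    const double dNx = 0.125 * sx * (1 + sy * eta) * (1 + sz * zeta) * s;
    const double dNy = 0.125 * sy * (1 + sx * xi) * (1 + sz * zeta) * s;
    const double dNz = 0.125 * sz * (1 + sx * xi) * (1 + sy * eta) * s;
    B[0][3 * i]     = dNx;
    B[1][3 * i + 1] = dNy;
    B[2][3 * i + 2] = dNz;
    B[3][3 * i]     = dNy; B[3][3 * i + 1] = dNx;
    B[4][3 * i + 1] = dNz; B[4][3 * i + 2] = dNy;
    B[5][3 * i]     = dNz; B[5][3 * i + 2] = dNx;
  }
}

static void iso_D(double nu, double D[6][6]) {
  // isotropic elasticity for unit Young's modulus, engineering shear strains
  const double lam = nu / ((1 + nu) * (1 - 2 * nu));
  const double mu = 1.0 / (2.0 * (1 + nu));
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 6; ++c) D[r][c] = 0.0;
  for (int r = 0; r < 3; ++r) {
    for (int c = 0; c < 3; ++c) D[r][c] = lam;
    D[r][r] = lam + 2 * mu;
    D[r + 3][r + 3] = mu;
  }
}

// 24x24 stiffness of a cube element of edge h for unit Young's modulus,
// trilinear shape functions, full 2x2x2 Gauss integration.
// [[Rcpp::export]]
NumericMatrix cpp_hex_stiffness(double h, double nu) {
  NumericMatrix K(24, 24);
  double D[6][6], B[6][24];
  iso_D(nu, D);
  const double g = 1.0 / std::sqrt(3.0);
  const double detJ = (h / 2) * (h / 2) * (h / 2);
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b)
      for (int c = 0; c < 2; ++c) {
        hex_B(a ? g : -g, b ? g : -g, c ? g : -g, h, B);
        double DB[6][24];
        for (int r = 0; r < 6; ++r)
          for (int j = 0; j < 24; ++j) {
            double acc = 0;
            for (int k = 0; k < 6; ++k) acc += D[r][k] * B[k][j];
            DB[r][j] = acc;
          }
        for (int i = 0; i < 24; ++i)
          for (int j = 0; j < 24; ++j) {
            double acc = 0;
            for (int r = 0; r < 6; ++r) acc += B[r][i] * DB[r][j];
            K(i, j) += acc * detJ;
          }
      }
  return K;
}

// y = K u over the whole mesh (element-by-element, Ke = E_e * K0)
static void fe_matvec(const double *u, double *y, R_xlen_t ndof,
                      const IntegerMatrix &en, const double *E,
                      const double *K0, int nelem) {
  for (R_xlen_t i = 0; i < ndof; ++i) y[i] = 0.0;
  double xe[24], ye[24];
  for (int e = 0; e < nelem; ++e) {
    int dof[24];
    for (int a = 0; a < 8; ++a) {
      const int nid = en(e, a);
      dof[3 * a] = 3 * nid; dof[3 * a + 1] = 3 * nid + 1;
      dof[3 * a + 2] = 3 * nid + 2;
    }
    for (int a = 0; a < 24; ++a) xe[a] = u[dof[a]];
    const double Ee = E[e];
    for (int i = 0; i < 24; ++i) {
      double acc = 0;
      const double *row = K0 + (R_xlen_t)24 * i; // K0 column i (symmetric)
      for (int j = 0; j < 24; ++j) acc += row[j] * xe[j];
      ye[i] = Ee * acc;
    }
    for (int a = 0; a < 24; ++a) y[dof[a]] += ye[a];
  }
}

// [[Rcpp::export]]
NumericVector cpp_fe_matvec(NumericVector u, IntegerMatrix elem_nodes,
                            NumericVector Evec, NumericMatrix K0) {
  NumericVector y(u.size());
  fe_matvec(u.begin(), y.begin(), u.size(), elem_nodes, Evec.begin(),
            K0.begin(), elem_nodes.nrow());
  return y;
}

// Jacobi-preconditioned CG on the free dofs. `fixed` flags constrained dofs,
// `u0` carries their prescribed values (zero elsewhere).
// [[Rcpp::export]]
List cpp_fe_solve(IntegerMatrix elem_nodes, NumericVector Evec,
                  NumericMatrix K0, int ndof, LogicalVector fixed,
                  NumericVector u0, double tol, int maxit) {
  const int nelem = elem_nodes.nrow();
  std::vector<double> u(ndof), r(ndof), z(ndof), p(ndof), q(ndof), d(ndof, 0.0);
  for (int i = 0; i < ndof; ++i) u[i] = u0[i];
  // diagonal of K for the Jacobi preconditioner
  for (int e = 0; e < nelem; ++e)
    for (int a = 0; a < 8; ++a) {
      const int nid = elem_nodes(e, a);
      for (int c = 0; c < 3; ++c)
        d[3 * nid + c] += Evec[e] * K0(3 * a + c, 3 * a + c);
    }
  // r = -(K u0) on free dofs
  fe_matvec(u.data(), r.data(), ndof, elem_nodes, Evec.begin(), K0.begin(),
            nelem);
  double rr0 = 0.0;
  for (int i = 0; i < ndof; ++i) {
    r[i] = fixed[i] ? 0.0 : -r[i];
    rr0 += r[i] * r[i];
  }
  const double rnorm0 = std::sqrt(rr0);
  double relres = 0.0;
  int it = 0;
  bool conv = true;
  if (rnorm0 > 0) {
    conv = false;
    double rz = 0.0;
    for (int i = 0; i < ndof; ++i) {
      z[i] = fixed[i] ? 0.0 : r[i] / (d[i] > 0 ? d[i] : 1.0);
      p[i] = z[i];
      rz += r[i] * z[i];
    }
    for (it = 1; it <= maxit; ++it) {
      fe_matvec(p.data(), q.data(), ndof, elem_nodes, Evec.begin(), K0.begin(),
                nelem);
      double pq = 0.0;
      for (int i = 0; i < ndof; ++i) {
        if (fixed[i]) q[i] = 0.0;
        pq += p[i] * q[i];
      }
      const double alpha = rz / pq;
      double rr = 0.0;
      for (int i = 0; i < ndof; ++i) {
        u[i] += alpha * p[i];
        r[i] -= alpha * q[i];
        rr += r[i] * r[i];
      }
      relres = std::sqrt(rr) / rnorm0;
      if (relres <= tol) { conv = true; break; }
      double rz_new = 0.0;
      for (int i = 0; i < ndof; ++i) {
        z[i] = fixed[i] ? 0.0 : r[i] / (d[i] > 0 ? d[i] : 1.0);
        rz_new += r[i] * z[i];
      }
      const double beta = rz_new / rz;
      rz = rz_new;
      for (int i = 0; i < ndof; ++i) p[i] = z[i] + beta * p[i];
      if (it % 200 == 0) Rcpp::checkUserInterrupt();
    }
    if (it > maxit) it = maxit;
  }
  NumericVector uo(ndof);
  for (int i = 0; i < ndof; ++i) uo[i] = u[i];
  return List::create(_["u"] = uo, _["iterations"] = it,
                      _["relative_residual"] = relres, _["converged"] = conv);
}

// Per-element strain energy density at the element centroid, SED = 0.5 e' C e
// with C = E_e * D(nu). Units: MPa when E is MPa and displacements mm.
// [[Rcpp::export]]
NumericVector cpp_element_sed(NumericVector u, IntegerMatrix elem_nodes,
                              NumericVector Evec, double h, double nu) {
  const int nelem = elem_nodes.nrow();
  NumericVector sed(nelem);
  double D[6][6], B[6][24];
  iso_D(nu, D);
  hex_B(0.0, 0.0, 0.0, h, B);
  double ue[24], eps[6], sig[6];
  for (int e = 0; e < nelem; ++e) {
    for (int a = 0; a < 8; ++a) {
      const int nid = elem_nodes(e, a);
      ue[3 * a] = u[3 * nid]; ue[3 * a + 1] = u[3 * nid + 1];
      ue[3 * a + 2] = u[3 * nid + 2];
    }
    for (int r = 0; r < 6; ++r) {
      double acc = 0;
      for (int j = 0; j < 24; ++j) acc += B[r][j] * ue[j];
      eps[r] = acc;
    }
    double en = 0.0;
    for (int r = 0; r < 6; ++r) {
      double acc = 0;
      for (int c = 0; c < 6; ++c) acc += D[r][c] * eps[c];
      sig[r] = Evec[e] * acc;
      en += sig[r] * eps[r];
    }
    sed[e] = 0.5 * en;
  }
  return sed;
}
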