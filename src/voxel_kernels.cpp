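// Voxel-level kernels shared by the quantification modules.
// Arrays arrive from R in (z, y, x) dimension order, column-major,
// so index (iz, iy, ix) lives at iz + nz*(iy + ny*ix).
#include <RcppArmadillo.h>
#include <queue>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double BIG = 1e20;

// One-dimensional squared-distance transform along a sampled line with
// physical spacing w (lower-envelope-of-parabolas algorithm).
static void dt1d(const double* f, double* d, int* v, double* z, int n, double w) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    const double xq = q * w;
    double s;
    for (;;) {
      const double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * w;
    while (z[k + 1] < xq) ++k;
    const double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact anisotropic squared Euclidean distance transform of a 3D mask.
// mask != 0 marks feature-free (tissue) voxels whose distance to the
// nearest zero voxel is sought; zeros are the distance-zero set.
// [[Rcpp::export]]
NumericVector edt_squared_cpp(IntegerVector mask, IntegerVector dims,
                              NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double wz = spacing[0], wy = spacing[1], wx = spacing[2];
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = mask[i] ? BIG : 0.0;

  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass 1: along z
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy) {
      double* col = &out[(R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)];
      for (int iz = 0; iz < nz; ++iz) f[iz] = col[iz];
      dt1d(f.data(), d.data(), v.data(), z.data(), nz, wz);
      for (int iz = 0; iz < nz; ++iz) col[iz] = d[iz];
    }
  // pass 2: along y
  for (int ix = 0; ix < nx; ++ix)
    for (int iz = 0; iz < nz; ++iz) {
      for (int iy = 0; iy < ny; ++iy)
        f[iy] = out[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)];
      dt1d(f.data(), d.data(), v.data(), z.data(), ny, wy);
      for (int iy = 0; iy < ny; ++iy)
        out[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)] = d[iy];
    }
  // pass 3: along x
  for (int iy = 0; iy < ny; ++iy)
    for (int iz = 0; iz < nz; ++iz) {
      for (int ix = 0; ix < nx; ++ix)
        f[ix] = out[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)];
      dt1d(f.data(), d.data(), v.data(), z.data(), nx, wx);
      for (int ix = 0; ix < nx; ++ix)
        out[iz + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix)] = d[ix];
    }
  return out;
}

// 26-connected component labeling of a 3D binary mask.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(ntot, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int iz = cur % nz;
      const int iy = (cur / nz) % ny;
      const int ix = cur / ((R_xlen_t)nz * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            const int jz = iz + dz, jy = iy + dy, jx = ix + dx;
            if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 || jx >= nx)
              continue;
            const R_xlen_t t = jz + (R_xlen_t)nz * (jy + (R_xlen_t)ny * jx);
            if (mask[t] && !lab[t]) {
              lab[t] = next;
              stack.push_back(t);
            }
          }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Maximum pairwise Euclidean distance over a set of points (rows of
// coords, already in physical units). Used for max Feret diameter.
// [[Rcpp::export]]
double max_pairwise_dist_cpp(NumericMatrix coords) {
  const int n = coords.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) {
        const double d = coords(i, k) - coords(j, k);
        s += d * d;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}

// Running window extreme over each column of a matrix, window half-width k,
// replicate boundary (clamped indices). maximum = true for dilation.
// [[Rcpp::export]]
NumericMatrix roll_extreme_cols_cpp(NumericMatrix m, int k, bool maximum) {
  const int n = m.nrow(), p = m.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) {
      const int lo = std::max(0, i - k), hi = std::min(n - 1, i + k);
      double e = m(lo, j);
      for (int q = lo + 1; q <= hi; ++q)
        e = maximum ? std::max(e, m(q, j)) : std::min(e, m(q, j));
      out(i, j) = e;
    }
  return out;
}

// 2D median filter with square kernel of half-width k, replicate boundary.
// [[Rcpp::export]]
NumericMatrix median_filter2d_cpp(NumericMatrix m, int k) {
  const int n = m.nrow(), p = m.ncol();
  NumericMatrix out(n, p);
  std::vector<double> buf;
  buf.reserve((2 * k + 1) * (2 * k + 1));
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) {
      buf.clear();
      for (int jj = std::max(0, j - k); jj <= std::min(p - 1, j + k); ++jj)
        for (int ii = std::max(0, i - k); ii <= std::min(n - 1, i + k); ++ii)
          buf.push_back(m(ii, jj));
      const size_t h = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + h, buf.end());
      double med = buf[h];
      if (buf.size() % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + h - 1, buf.begin() + h);
        med = 0.5 * (med + buf[h - 1]);
      }
      out(i, j) = med;
    }
  return out;
}

// Per-voxel eigen-analysis of the 3x3 symmetric structure tensor given by
// its six unique components. Returns the eigenvector of the smallest
// eigenvalue (fiber direction), a coherence score, and a degeneracy flag.
// [[Rcpp::export]]
List tensor_eigen_cpp(NumericVector jzz, NumericVector jzy, NumericVector jzx,
                      NumericVector jyy, NumericVector jyx, NumericVector jxx,
                      double degenerate_tol) {
  const R_xlen_t n = jzz.size();
  NumericVector vz(n), vy(n), vx(n), coh(n);
  LogicalVector degen(n);
  arma::mat33 J;
  arma::vec3 eval;
  arma::mat33 evec;
  for (R_xlen_t i = 0; i < n; ++i) {
    J(0, 0) = jzz[i]; J(0, 1) = jzy[i]; J(0, 2) = jzx[i];
    J(1, 0) = jzy[i]; J(1, 1) = jyy[i]; J(1, 2) = jyx[i];
    J(2, 0) = jzx[i]; J(2, 1) = jyx[i]; J(2, 2) = jxx[i];
    arma::eig_sym(eval, evec, J);   // eigenvalues ascending
    const double lmin = eval[0], lmid = eval[1], lmax = eval[2];
    const double tot = lmin + lmid + lmax;
    const bool dg = (lmax - lmin) <= degenerate_tol * std::max(1e-300, std::abs(tot));
    degen[i] = dg;
    coh[i] = (tot > 0.0) ? (lmid - lmin) / tot : 0.0;
    vz[i] = evec(0, 0);
    vy[i] = evec(1, 0);
    vx[i] = evec(2, 0);
  }
  return List::create(_["vz"] = vz, _["vy"] = vy, _["vx"] = vx,
                      _["coherence"] = coh, _["degenerate"] = degen);
}

// Explicit finite-difference reference solver for pure radial diffusion
// in cylindrical symmetry on a uniform grid: independent oracle for the
// method-of-lines solver in the zero-kinetics limit. Central differences
// on the expanded form u_t = D (u_rr + u_r / r); Dirichlet at r_max,
// symmetry at r = 0.
// [[Rcpp::export]]
NumericVector radial_diffusion_explicit_cpp(NumericVector u0, double D,
                                            double r_max, double t_end,
                                            double boundary_value,
                                            double safety) {
  const int n = u0.size();
  const double dr = r_max / (n - 1);
  double dt = safety * dr * dr / D;
  const R_xlen_t nsteps = (R_xlen_t)std::ceil(t_end / dt);
  dt = t_end / nsteps;
  std::vector<double> u(u0.begin(), u0.end()), un(n);
  u[n - 1] = boundary_value;
  for (R_xlen_t s = 0; s < nsteps; ++s) {
    un[0] = u[0] + dt * 4.0 * D * (u[1] - u[0]) / (dr * dr);
    for (int j = 1; j < n - 1; ++j) {
      const double r = j * dr;
      const double urr = (u[j + 1] - 2.0 * u[j] + u[j - 1]) / (dr * dr);
      const double ur = (u[j + 1] - u[j - 1]) / (2.0 * dr);
      un[j] = u[j] + dt * D * (urr + ur / r);
    }
    un[n - 1] = boundary_value;
    u.swap(un);
  }
  return NumericVector(u.begin(), u.end());
}
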