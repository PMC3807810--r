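#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Volumes are column-major 3D arrays; voxel (i,j,k) (0-based) lives at
// world position origin + (i,j,k) * spacing (axis-aligned grids only).

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long)ny * k) ;
}

// Pull-back resampling: out(p) = in(T p) with T mapping output-world
// coordinates to input-world coordinates. Points outside the input
// support take `fill`.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vals, IntegerVector dim_in,
                           NumericVector sp_in, NumericVector or_in,
                           IntegerVector dim_out, NumericVector sp_out,
                           NumericVector or_out, NumericMatrix T,
                           bool nearest, double fill) {
  const int nxi = dim_in[0], nyi = dim_in[1], nzi = dim_in[2];
  const int nxo = dim_out[0], nyo = dim_out[1], nzo = dim_out[2];
  NumericVector out((R_xlen_t)nxo * nyo * nzo);
  for (int k = 0; k < nzo; ++k) {
    for (int j = 0; j < nyo; ++j) {
      for (int i = 0; i < nxo; ++i) {
        double px = or_out[0] + i * sp_out[0];
        double py = or_out[1] + j * sp_out[1];
        double pz = or_out[2] + k * sp_out[2];
        double qx = T(0,0)*px + T(0,1)*py + T(0,2)*pz + T(0,3);
        double qy = T(1,0)*px + T(1,1)*py + T(1,2)*pz + T(1,3);
        double qz = T(2,0)*px + T(2,1)*py + T(2,2)*pz + T(2,3);
        double cx = (qx - or_in[0]) / sp_in[0];
        double cy = (qy - or_in[1]) / sp_in[1];
        double cz = (qz - or_in[2]) / sp_in[2];
        double v = fill;
        if (nearest) {
          int ii = (int)std::lround(cx);
          int jj = (int)std::lround(cy);
          int kk = (int)std::lround(cz);
          if (ii >= 0 && ii < nxi && jj >= 0 && jj < nyi && kk >= 0 && kk < nzi)
            v = vals[idx3(ii, jj, kk, nxi, nyi)];
        } else {
          int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy),
              k0 = (int)std::floor(cz);
          if (i0 >= 0 && i0 + 1 < nxi && j0 >= 0 && j0 + 1 < nyi &&
              k0 >= 0 && k0 + 1 < nzi) {
            double fx = cx - i0, fy = cy - j0, fz = cz - k0;
            double v000 = vals[idx3(i0,   j0,   k0,   nxi, nyi)];
            double v100 = vals[idx3(i0+1, j0,   k0,   nxi, nyi)];
            double v010 = vals[idx3(i0,   j0+1, k0,   nxi, nyi)];
            double v110 = vals[idx3(i0+1, j0+1, k0,   nxi, nyi)];
            double v001 = vals[idx3(i0,   j0,   k0+1, nxi, nyi)];
            double v101 = vals[idx3(i0+1, j0,   k0+1, nxi, nyi)];
            double v011 = vals[idx3(i0,   j0+1, k0+1, nxi, nyi)];
            double v111 = vals[idx3(i0+1, j0+1, k0+1, nxi, nyi)];
            v = (1-fz) * ((1-fy)*((1-fx)*v000 + fx*v100) +
                          fy    *((1-fx)*v010 + fx*v110)) +
                fz     * ((1-fy)*((1-fx)*v001 + fx*v101) +
                          fy    *((1-fx)*v011 + fx*v111));
          } else if (i0 >= -1 && i0 < nxi && j0 >= -1 && j0 < nyi &&
                     k0 >= -1 && k0 < nzi) {
            // boundary cell: trilinear with out-of-range corners = fill
            double fx = cx - i0, fy = cy - j0, fz = cz - k0;
            double acc = 0.0;
            for (int dk = 0; dk <= 1; ++dk)
              for (int dj = 0; dj <= 1; ++dj)
                for (int di = 0; di <= 1; ++di) {
                  int ii = i0 + di, jj = j0 + dj, kk = k0 + dk;
                  double w = (di ? fx : 1-fx) * (dj ? fy : 1-fy) *
                             (dk ? fz : 1-fz);
                  double cv = fill;
                  if (ii >= 0 && ii < nxi && jj >= 0 && jj < nyi &&
                      kk >= 0 && kk < nzi)
                    cv = vals[idx3(ii, jj, kk, nxi, nyi)];
                  acc += w * cv;
                }
            v = acc;
          }
        }
        out[idx3(i, j, k, nxo, nyo)] = v;
      }
    }
  }
  return out;
}

// Separable Gaussian filtering with reflective (mirror) boundary.
// sigma_vox gives the per-axis standard deviation in voxels; kernels are
// sampled Gaussians normalised to sum 1, truncated at 4 sigma.
static void smooth_axis(std::vector<double>& v, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) {
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + r];
  }
  for (double& kv : ker) kv /= s;
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> line(n), res(n);
  int n_outer1, n_outer2;
  if (axis == 0)      { n_outer1 = ny; n_outer2 = nz; }
  else if (axis == 1) { n_outer1 = nx; n_outer2 = nz; }
  else                { n_outer1 = nx; n_outer2 = ny; }
  for (int b = 0; b < n_outer2; ++b) {
    for (int a = 0; a < n_outer1; ++a) {
      for (int t = 0; t < n; ++t) {
        int i, j, k;
        if (axis == 0)      { i = t; j = a; k = b; }
        else if (axis == 1) { i = a; j = t; k = b; }
        else                { i = a; j = b; k = t; }
        line[t] = v[idx3(i, j, k, nx, ny)];
      }
      for (int t = 0; t < n; ++t) {
        double acc = 0;
        for (int u = -r; u <= r; ++u) {
          int tt = t + u;
          // reflect (half-sample symmetric enough: mirror without repeat)
          while (tt < 0 || tt >= n) {
            if (tt < 0) tt = -tt - 1;
            if (tt >= n) tt = 2 * n - tt - 1;
          }
          acc += ker[u + r] * line[tt];
        }
        res[t] = acc;
      }
      for (int t = 0; t < n; ++t) {
        int i, j, k;
        if (axis == 0) { i = t; j = a; k = b; }
        else if (axis == 1) { i = a; j = t; k = b; }
        else { i = a; j = b; k = t; }
        v[idx3(i, j, k, nx, ny)] = res[t];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vals, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vals.begin(), vals.end());
  smooth_axis(v, nx, ny, nz, 0, sigma_vox[0]);
  smooth_axis(v, nx, ny, nz, 1, sigma_vox[1]);
  smooth_axis(v, nx, ny, nz, 2, sigma_vox[2]);
  return NumericVector(v.begin(), v.end());
}

// 1D squared-distance transform of sampled function f at positions t*step
// (Felzenszwalb & Huttenlocher lower envelope of parabolas).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
  std::vector<int> vi(n);
  std::vector<double> z(n + 1);
  int k = 0;
  vi[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    while (true) {
      double xv = vi[k] * step;
      double s = ((f[q] + xq * xq) - (f[vi[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; }
      else {
        ++k; vi[k] = q; z[k] = s; z[k + 1] =
          std::numeric_limits<double>::infinity();
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double dx = xq - vi[k] * step;
    d[q] = dx * dx + f[vi[k]];
  }
}

// Exact Euclidean distance transform (mm) on an anisotropic grid:
// distance from every voxel to the nearest voxel with mask != 0.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite stand-in for +inf keeps the parabola intersections finite
  const double INF = 1e20;
  std::vector<double> g((size_t)nx * ny * nz);
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    g[i] = mask[i] != 0 ? 0.0 : INF;
  // x pass
  {
    std::vector<double> f(nx), d(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) f[i] = g[idx3(i,j,k,nx,ny)];
        dt1d(f, d, nx, spacing[0]);
        for (int i = 0; i < nx; ++i) g[idx3(i,j,k,nx,ny)] = d[i];
      }
  }
  // y pass
  {
    std::vector<double> f(ny), d(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) f[j] = g[idx3(i,j,k,nx,ny)];
        dt1d(f, d, ny, spacing[1]);
        for (int j = 0; j < ny; ++j) g[idx3(i,j,k,nx,ny)] = d[j];
      }
  }
  // z pass
  {
    std::vector<double> f(nz), d(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) f[k] = g[idx3(i,j,k,nx,ny)];
        dt1d(f, d, nz, spacing[2]);
        for (int k = 0; k < nz; ++k) g[idx3(i,j,k,nx,ny)] = d[k];
      }
  }
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Connected-component labelling (6- or 26-connectivity), labels 1..n by
// discovery order; 0 outside the mask.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back((int)s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int k = cur / (nx * ny);
      int rem = cur % (nx * ny);
      int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 &&
                std::abs(di) + std::abs(dj) + std::abs(dk) > 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny ||
                kk < 0 || kk >= nz) continue;
            int t = idx3(ii, jj, kk, nx, ny);
            if (mask[t] != 0 && lab[t] == 0) {
              lab[t] = next;
              stack.push_back(t);
            }
          }
    }
  }
  return lab;
}
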