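#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline long idx3(int i, int j, int k, int nx, int ny) {
  return i + (long)nx * (j + (long)ny * k);
}

// Gaussian PSF coupling between a thick-slice stack grid and the
// reconstruction grid. Acquired voxel j at stack-world position p maps to
// recon world q = pose(p); reconstruction voxels i inside the 3-sigma
// support contribute with weights m_ij proportional to a Gaussian in the
// stack frame (Rinv rotates world displacements back into stack axes),
// normalised so sum_i m_ij = 1.
//
// mode 0 (forward):  out[j]   = sum_i m_ij * vol[i]       (simulate slices)
// mode 1 (adjoint):  out[i]  += sum_j stackv[j] * m_ij    (scatter)
// Forward output for acquired voxels with empty support is NA.
// [[Rcpp::export]]
NumericVector cpp_psf_apply(NumericVector vol, IntegerVector vdim,
                            NumericVector vsp, NumericVector vor,
                            IntegerVector sdim, NumericVector ssp,
                            NumericVector sor, NumericMatrix pose,
                            NumericMatrix Rinv, NumericVector sigma,
                            int mode, NumericVector stackv) {
  int vnx = vdim[0], vny = vdim[1], vnz = vdim[2];
  int snx = sdim[0], sny = sdim[1], snz = sdim[2];
  // per-world-axis support bound covering the rotated 3-sigma box
  double sw[3];
  for (int i = 0; i < 3; ++i) {
    double s = 0;
    for (int j = 0; j < 3; ++j)
      s += std::fabs(pose(i, j)) * sigma[j];
    sw[i] = s;
  }
  int rx = std::max(1, (int)std::ceil(3.0 * sw[0] / vsp[0]));
  int ry = std::max(1, (int)std::ceil(3.0 * sw[1] / vsp[1]));
  int rz = std::max(1, (int)std::ceil(3.0 * sw[2] / vsp[2]));
  R_xlen_t nout = (mode == 0) ? (R_xlen_t)snx * sny * snz
                              : (R_xlen_t)vnx * vny * vnz;
  NumericVector out(nout);
  if (mode == 0) std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<long> nb_idx; nb_idx.reserve(512);
  std::vector<double> nb_w; nb_w.reserve(512);
  for (int sk = 0; sk < snz; ++sk)
    for (int sj = 0; sj < sny; ++sj)
      for (int si = 0; si < snx; ++si) {
        double px = sor[0] + si * ssp[0];
        double py = sor[1] + sj * ssp[1];
        double pz = sor[2] + sk * ssp[2];
        double qx = pose(0,0)*px + pose(0,1)*py + pose(0,2)*pz + pose(0,3);
        double qy = pose(1,0)*px + pose(1,1)*py + pose(1,2)*pz + pose(1,3);
        double qz = pose(2,0)*px + pose(2,1)*py + pose(2,2)*pz + pose(2,3);
        int ci = (int)std::lround((qx - vor[0]) / vsp[0]);
        int cj = (int)std::lround((qy - vor[1]) / vsp[1]);
        int ck = (int)std::lround((qz - vor[2]) / vsp[2]);
        nb_idx.clear(); nb_w.clear();
        double wsum = 0;
        for (int dk = -rz; dk <= rz; ++dk) {
          int kk = ck + dk;
          if (kk < 0 || kk >= vnz) continue;
          for (int dj = -ry; dj <= ry; ++dj) {
            int jj = cj + dj;
            if (jj < 0 || jj >= vny) continue;
            for (int di = -rx; di <= rx; ++di) {
              int ii = ci + di;
              if (ii < 0 || ii >= vnx) continue;
              double wx = vor[0] + ii * vsp[0] - qx;
              double wy = vor[1] + jj * vsp[1] - qy;
              double wz = vor[2] + kk * vsp[2] - qz;
              double dx = Rinv(0,0)*wx + Rinv(0,1)*wy + Rinv(0,2)*wz;
              double dy = Rinv(1,0)*wx + Rinv(1,1)*wy + Rinv(1,2)*wz;
              double dz = Rinv(2,0)*wx + Rinv(2,1)*wy + Rinv(2,2)*wz;
              if (std::fabs(dx) > 3*sigma[0] || std::fabs(dy) > 3*sigma[1]
                  || std::fabs(dz) > 3*sigma[2]) continue;
              double g = std::exp(-0.5 * (dx*dx/(sigma[0]*sigma[0]) +
                                          dy*dy/(sigma[1]*sigma[1]) +
                                          dz*dz/(sigma[2]*sigma[2])));
              nb_idx.push_back(idx3(ii, jj, kk, vnx, vny));
              nb_w.push_back(g);
              wsum += g;
            }
          }
        }
        if (wsum <= 0) continue;
        long j = idx3(si, sj, sk, snx, sny);
        if (mode == 0) {
          double acc = 0;
          for (size_t q = 0; q < nb_idx.size(); ++q)
            acc += nb_w[q] / wsum * vol[nb_idx[q]];
          out[j] = acc;
        } else {
          double sv = stackv[j];
          if (ISNA(sv)) continue;
          for (size_t q = 0; q < nb_idx.size(); ++q)
            out[nb_idx[q]] += sv * nb_w[q] / wsum;
        }
      }
  return out;
}
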