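#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline long idx3(int i, int j, int k, int nx, int ny) {
  return i + (long)nx * (j + (long)ny * k);
}

// Lattice of cubic blocks (radius br, step voxels) fully inside the image.
// keep rule: variance > 0 when thr < 0, else variance >= thr.
// Returns centres (0-based voxel indices) and variances.
// [[Rcpp::export]]
List cpp_select_blocks(NumericVector vals, IntegerVector dim,
                       int br, int step, double thr) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int bn = 2 * br + 1, bsz = bn * bn * bn;
  std::vector<int> ci, cj, ck;
  std::vector<double> vars;
  for (int k = br; k + br < nz; k += step)
    for (int j = br; j + br < ny; j += step)
      for (int i = br; i + br < nx; i += step) {
        double s = 0, s2 = 0;
        for (int dk = -br; dk <= br; ++dk)
          for (int dj = -br; dj <= br; ++dj)
            for (int di = -br; di <= br; ++di) {
              double v = vals[idx3(i + di, j + dj, k + dk, nx, ny)];
              s += v; s2 += v * v;
            }
        double var = s2 / bsz - (s / bsz) * (s / bsz);
        bool keep = (thr < 0) ? (var > 0) : (var >= thr);
        if (keep) { ci.push_back(i); cj.push_back(j); ck.push_back(k);
                    vars.push_back(var); }
      }
  int n = (int)ci.size();
  IntegerMatrix centres(n, 3);
  NumericVector v(n);
  for (int t = 0; t < n; ++t) {
    centres(t, 0) = ci[t]; centres(t, 1) = cj[t]; centres(t, 2) = ck[t];
    v[t] = vars[t];
  }
  return List::create(_["centres"] = centres, _["variance"] = v);
}

// Exhaustive integer-offset block search. For each source block centre the
// current transform T (source world -> target world) gives the search
// centre in the target; offsets in [-r, r]^3 are scanned and the block
// maximising NCC (or squared NCC when cr = true) among target blocks with
// variance >= tvar_thr wins. Ties: smaller |offset|, then lexicographic
// (ox, oy, oz). Output rows: valid, Cx, Cy, Cz (source world), dx, dy, dz
// (matched target point minus source centroid, mm), score.
// [[Rcpp::export]]
NumericMatrix cpp_match_blocks(NumericVector src, IntegerVector sdim,
                               NumericVector ssp, NumericVector sor,
                               NumericVector tgt, IntegerVector tdim,
                               NumericVector tsp, NumericVector tor,
                               IntegerMatrix centres, NumericMatrix T,
                               int br, int r, double tvar_thr, bool cr) {
  int snx = sdim[0], sny = sdim[1];
  int tnx = tdim[0], tny = tdim[1], tnz = tdim[2];
  int bn = 2 * br + 1, bsz = bn * bn * bn;
  int n = centres.nrow();
  NumericMatrix out(n, 8);
  std::vector<double> a(bsz);
  // integral images of the target (sum and sum of squares) give each
  // candidate block's mean/variance in O(1), so featureless candidates
  // are rejected without touching their voxels
  long inx = tnx + 1, iny = tny + 1, inz = tnz + 1;
  std::vector<double> I1((size_t)inx * iny * inz, 0.0);
  std::vector<double> I2((size_t)inx * iny * inz, 0.0);
  for (int k = 1; k < inz; ++k)
    for (int j = 1; j < iny; ++j)
      for (int i = 1; i < inx; ++i) {
        size_t c = i + inx * (j + (long)iny * k);
        double v = tgt[idx3(i - 1, j - 1, k - 1, tnx, tny)];
        I1[c] = v + I1[c - 1] + I1[c - inx] + I1[c - inx * iny]
          - I1[c - 1 - inx] - I1[c - 1 - inx * iny]
          - I1[c - inx - inx * iny] + I1[c - 1 - inx - inx * iny];
        double v2 = v * v;
        I2[c] = v2 + I2[c - 1] + I2[c - inx] + I2[c - inx * iny]
          - I2[c - 1 - inx] - I2[c - 1 - inx * iny]
          - I2[c - inx - inx * iny] + I2[c - 1 - inx - inx * iny];
      }
  auto box = [&](const std::vector<double>& I, int i0, int j0, int k0) {
    // sum over [i0, i0+bn) x [j0, j0+bn) x [k0, k0+bn), 0-based voxels
    size_t a000 = (size_t)i0 + inx * (j0 + (long)iny * k0);
    size_t a111 = (size_t)(i0 + bn) + inx * ((j0 + bn) +
                  (long)iny * (k0 + bn));
    return I[a111]
      - I[(size_t)i0 + inx * ((j0 + bn) + (long)iny * (k0 + bn))]
      - I[(size_t)(i0 + bn) + inx * (j0 + (long)iny * (k0 + bn))]
      - I[(size_t)(i0 + bn) + inx * ((j0 + bn) + (long)iny * k0)]
      + I[(size_t)(i0 + bn) + inx * (j0 + (long)iny * k0)]
      + I[(size_t)i0 + inx * ((j0 + bn) + (long)iny * k0)]
      + I[(size_t)i0 + inx * (j0 + (long)iny * (k0 + bn))]
      - I[a000];
  };
  for (int t = 0; t < n; ++t) {
    int si = centres(t, 0), sj = centres(t, 1), sk = centres(t, 2);
    // source block, centred stats
    double sa = 0;
    int u = 0;
    for (int dk = -br; dk <= br; ++dk)
      for (int dj = -br; dj <= br; ++dj)
        for (int di = -br; di <= br; ++di)
          { a[u] = src[idx3(si + di, sj + dj, sk + dk, snx, sny)];
            sa += a[u]; ++u; }
    double ma = sa / bsz, va = 0;
    for (int q = 0; q < bsz; ++q) { a[q] -= ma; va += a[q] * a[q]; }
    if (va <= 0) { out(t, 0) = 0; continue; }
    double px = sor[0] + si * ssp[0];
    double py = sor[1] + sj * ssp[1];
    double pz = sor[2] + sk * ssp[2];
    double qx = T(0,0)*px + T(0,1)*py + T(0,2)*pz + T(0,3);
    double qy = T(1,0)*px + T(1,1)*py + T(1,2)*pz + T(1,3);
    double qz = T(2,0)*px + T(2,1)*py + T(2,2)*pz + T(2,3);
    int ti0 = (int)std::lround((qx - tor[0]) / tsp[0]);
    int tj0 = (int)std::lround((qy - tor[1]) / tsp[1]);
    int tk0 = (int)std::lround((qz - tor[2]) / tsp[2]);
    double best = -2.0, bestd2 = 0;
    int bo[3] = {0, 0, 0};
    bool found = false;
    for (int oz = -r; oz <= r; ++oz)
      for (int oy = -r; oy <= r; ++oy)
        for (int ox = -r; ox <= r; ++ox) {
          int ci = ti0 + ox, cj = tj0 + oy, ck = tk0 + oz;
          if (ci - br < 0 || ci + br >= tnx || cj - br < 0 ||
              cj + br >= tny || ck - br < 0 || ck + br >= tnz) continue;
          double sb = box(I1, ci - br, cj - br, ck - br);
          double sbb = box(I2, ci - br, cj - br, ck - br);
          double vb = sbb - sb * sb / bsz;
          if (vb / bsz < tvar_thr || vb <= 0) continue;
          double sab = 0;
          int q = 0;
          for (int dk = -br; dk <= br; ++dk)
            for (int dj = -br; dj <= br; ++dj)
              for (int di = -br; di <= br; ++di) {
                sab += a[q] * tgt[idx3(ci + di, cj + dj, ck + dk, tnx, tny)];
                ++q;
              }
          double ncc = sab / std::sqrt(va * vb);
          double score = cr ? ncc * ncc : ncc;
          double d2 = (double)ox*ox + (double)oy*oy + (double)oz*oz;
          bool better = false;
          if (!found || score > best + 1e-12) better = true;
          else if (score > best - 1e-12) {
            if (d2 < bestd2 - 1e-12) better = true;
            else if (d2 < bestd2 + 1e-12) {
              if (ox < bo[0] || (ox == bo[0] && (oy < bo[1] ||
                  (oy == bo[1] && oz < bo[2])))) better = true;
            }
          }
          if (better) {
            best = score; bestd2 = d2;
            bo[0] = ox; bo[1] = oy; bo[2] = oz;
            found = true;
          }
        }
    if (!found) { out(t, 0) = 0; continue; }
    double mx = tor[0] + (ti0 + bo[0]) * tsp[0];
    double my = tor[1] + (tj0 + bo[1]) * tsp[1];
    double mz = tor[2] + (tk0 + bo[2]) * tsp[2];
    out(t, 0) = 1;
    out(t, 1) = px; out(t, 2) = py; out(t, 3) = pz;
    out(t, 4) = mx - px; out(t, 5) = my - py; out(t, 6) = mz - pz;
    out(t, 7) = best;
  }
  return out;
}
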